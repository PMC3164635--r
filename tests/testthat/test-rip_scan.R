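test_that("dinucleotide counting matches hand enumeration", {
  cd <- count_dinucleotides("TATA")
  expect_equal(cd$counts[["TA"]], 2L)
  expect_equal(cd$counts[["AT"]], 1L)
  expect_equal(cd$valid_pairs, 3L)

  expect_equal(count_dinucleotides("A")$valid_pairs, 0L)
  expect_equal(count_dinucleotides("")$valid_pairs, 0L)

  # pairs containing N are skipped but positions still advance
  cd <- count_dinucleotides("CNAC")
  expect_equal(cd$counts[["AC"]], 1L)
  expect_equal(cd$valid_pairs, 1L)
})

test_that("RIP indices follow the product/substrate definitions", {
  idx <- rip_indices(count_dinucleotides("TATA"))
  expect_equal(idx$product_index, 2)
  idx <- rip_indices(count_dinucleotides("CACA"))
  expect_equal(idx$substrate_index, 2)  # CA=2, TG=0, AC=1, GT=0
  idx <- rip_indices(count_dinucleotides("CCCC"))
  expect_true(is.na(idx$product_index))
  expect_true(is.na(idx$substrate_index))
  expect_equal(idx$at_content, 0)
})

test_that("counts and indices match the brute-force oracle on random input", {
  withr::local_seed(101)
  for (rep in 1:120) {
    s <- random_test_seq(sample(c(0:3, 10:400), 1),
                         gc = runif(1, 0.2, 0.8),
                         n_frac = sample(c(0, 0.02, 0.2), 1))
    got <- count_dinucleotides(s)
    idx <- rip_indices(got)
    want <- oracle_rip(s)
    expect_identical(got$counts, want$counts)
    expect_identical(got$valid_pairs, want$valid_pairs)
    expect_identical(idx$product_index, want$product_index)
    expect_identical(idx$substrate_index, want$substrate_index)
    expect_identical(idx$at_content, want$at_content)
  }
})

test_that("counts agree with Biostrings on N-free sequences", {
  withr::local_seed(55)
  for (rep in 1:20) {
    s <- random_test_seq(sample(2:500, 1), gc = runif(1, 0.2, 0.8))
    want <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(s))
    got <- count_dinucleotides(s)$counts
    expect_equal(got[names(want)], want, ignore_attr = TRUE)
  }
})

test_that("both indices are reverse-complement symmetric", {
  withr::local_seed(7)
  for (rep in 1:60) {
    s <- random_test_seq(sample(10:300, 1), gc = runif(1, 0.2, 0.8),
                         n_frac = 0.01)
    fwd <- rip_indices(count_dinucleotides(s))
    rev <- rip_indices(count_dinucleotides(revcomp(s)))
    expect_identical(fwd$product_index, rev$product_index)
    expect_identical(fwd$substrate_index, rev$substrate_index)
    expect_identical(fwd$at_content, rev$at_content)
  }
})

test_that("window scan emits full windows on the stated grid", {
  s <- random_genome(400, 0.5, seed = 1)
  w <- scan_windows(s, rip_params(200, 100))
  expect_equal(w$start, c(0, 100, 200))
  expect_equal(w$end, c(200, 300, 400))
  expect_equal(nrow(scan_windows(random_genome(150, 0.5, seed = 2),
                                 rip_params(200, 100))), 0L)
  # windowed values agree with direct per-window computation
  for (k in seq_len(nrow(w))) {
    sub <- extract_sequence(s, w$start[k], w$end[k])
    idx <- rip_indices(count_dinucleotides(sub))
    expect_equal(w$product_index[k], idx$product_index)
    expect_equal(w$substrate_index[k], idx$substrate_index)
    expect_equal(w$at_content[k], idx$at_content)
  }
})

test_that("windows with undefined indices are never RIP-positive", {
  s <- strrep("CG", 150)
  w <- scan_windows(s, rip_params(200, 100))
  expect_true(all(is.na(w$product_index)))
  expect_false(any(w$rip_positive))
})

test_that("thresholds are inclusive at the printed boundaries", {
  # product index exactly 0.89 = 89/100, substrate exactly 1.03 = 103/100:
  # construct a window from disjoint dinucleotide blocks separated by N,
  # so block counts are exact: 89 TA, 100 AT, 103 CA, 100 AC.
  block <- function(pair, times) {
    paste(rep(pair, times), collapse = "N")
  }
  s <- paste(block("TA", 89), block("AT", 100), block("CA", 103),
             block("AC", 100), sep = "N")
  cd <- count_dinucleotides(s)
  expect_equal(cd$counts[["TA"]], 89L)
  expect_equal(cd$counts[["AT"]], 100L)
  idx <- rip_indices(cd)
  expect_identical(idx$product_index, 0.89)
  expect_identical(idx$substrate_index, 1.03)
  pars <- rip_params(window = nchar(s), shift = nchar(s))
  w <- scan_windows(s, pars)
  expect_true(w$rip_positive[1])
  # one fewer TA or one more CA breaks the respective inclusive bound
  s2 <- paste(block("TA", 88), block("AT", 100), block("CA", 103),
              block("AC", 100), sep = "N")
  w2 <- scan_windows(s2, rip_params(nchar(s2), nchar(s2)))
  expect_false(w2$rip_positive[1])
  s3 <- paste(block("TA", 89), block("AT", 100), block("CA", 104),
              block("AC", 100), sep = "N")
  w3 <- scan_windows(s3, rip_params(nchar(s3), nchar(s3)))
  expect_false(w3$rip_positive[1])
})

test_that("re-scanning flags the same windows (no hidden state)", {
  g <- random_genome(5000, 0.45, seed = 33)
  g <- simulate_rip(g, intervals("genome", 0, 5000), 0.4, seed = 34)
  w1 <- scan_windows(g)
  w2 <- scan_windows(g)
  expect_identical(w1, w2)
  expect_true(any(w1$rip_positive))
})

test_that("RIP-positive fraction counts covered bases over total length", {
  w <- data.frame(contig = "c", start = c(0, 100, 500), end = c(200, 300, 700),
                  rip_positive = c(TRUE, TRUE, FALSE))
  expect_equal(rip_region_fraction(w, c(c = 1000)), 0.3)
  w$rip_positive <- FALSE
  expect_equal(rip_region_fraction(w, c(c = 1000)), 0)
  # per-genome aggregate is length-weighted across contigs
  w2 <- data.frame(contig = c("a", "b"), start = c(0, 0), end = c(200, 200),
                   rip_positive = c(TRUE, TRUE))
  expect_equal(rip_region_fraction(w2, c(a = 200, b = 600)), 0.5)
  expect_error(rip_region_fraction(w2, c(a = 0, b = 0)), "zero")
  expect_equal(rip_region_fraction(w, c(c = 1000), mode = "windows"), 0)
})

test_that("per-class summary pools counts without junction dinucleotides", {
  contigs <- c(c1 = "TATACCCC")
  part <- list(cls = intervals(c("c1", "c1"), c(0, 4), c(4, 8)))
  attr(part, "contig_lengths") <- c(c1 = 8)
  out <- summarize_by_class(contigs, part, settings = list(c(4L, 4L)))
  pooled <- out[out$scope == "pooled", ]
  # "TATA" + "CCCC": TA=2, AT=1 -> product 2; junction AC never counted
  expect_equal(pooled$product_index, 2)
  expect_equal(pooled$total_length, 8)
  wins <- out[out$scope == "windows", ]
  expect_equal(wins$n_windows, 2L)
})

test_that("whole-genome summary row matches a direct scan", {
  g <- c(ctg = random_genome(3000, 0.5, seed = 5))
  part <- list(whole_genome = intervals("ctg", 0, 3000))
  attr(part, "contig_lengths") <- c(ctg = 3000)
  out <- summarize_by_class(g, part, settings = list(c(200L, 100L)))
  direct <- scan_genome(g, rip_params(200, 100))
  row <- out[out$scope == "windows", ]
  expect_equal(row$n_windows, nrow(direct))
  expect_equal(row$frac_rip_positive, mean(direct$rip_positive))
  expect_equal(row$product_index, mean(direct$product_index, na.rm = TRUE))
  pooled <- out[out$scope == "pooled", ]
  expect_equal(pooled$product_index,
               rip_indices(count_dinucleotides(g[["ctg"]]))$product_index)
})

test_that("window tables serialize to BED6 and TSV", {
  g <- random_genome(600, 0.5, seed = 8)
  w <- scan_windows(g, contig_id = "ctg")
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_windows(w, bed = bed, tsv = tsv)
  b <- read.table(bed, sep = "\t")
  expect_equal(ncol(b), 6L)
  expect_equal(b[[2]], w$start)
  expect_equal(b[[5]], ifelse(is.na(w$product_index), 0,
                              pmin(1000, round(w$product_index * 1000))))
  t <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(t$substrate_index, w$substrate_index)
})
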