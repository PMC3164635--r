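# helpers to build small hit tables in code
hit_row <- function(q, s, pident = 80, len = 100, evalue = 1e-50,
                    bitscore = 200, qlen = 100, slen = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue, bitscore = bitscore,
             qlen = qlen, slen = slen, stringsAsFactors = FALSE)
}

toy_map <- function(ids) {
  data.frame(gene_id = ids, genome = sub("_.*", "", ids))
}

test_that("hit tables read with genomes resolved; missing lengths error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  h <- hit_row("A_1", "B_1")
  write.table(h, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  got <- read_hit_table(f, toy_map(c("A_1", "B_1")))
  expect_equal(nrow(got), 1L)
  expect_equal(got$query_genome, "A")
  expect_equal(got$subject_genome, "B")

  write.table(h[, 1:12], f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_hit_table(f, toy_map(c("A_1", "B_1"))), "lengths")
  got2 <- read_hit_table(f, toy_map(c("A_1", "B_1")),
                         lengths = c(A_1 = 100, B_1 = 100))
  expect_equal(got2$qlen, 100)

  expect_error(read_hit_table(f, toy_map("A_1"),
                              lengths = c(A_1 = 100, B_1 = 100)), "B_1")
})

test_that("homology filter applies inclusive thresholds on all three rules", {
  gm <- toy_map(c("A_1", "B_1"))
  keep <- function(h) nrow(filter_homologs(annotate_genomes(h, gm)))
  expect_equal(keep(hit_row("A_1", "B_1", pident = 45, len = 70,
                            evalue = 1e-6)), 1L)
  expect_equal(keep(hit_row("A_1", "B_1", pident = 29.9)), 0L)
  expect_equal(keep(hit_row("A_1", "B_1", pident = 30)), 1L)     # inclusive
  expect_equal(keep(hit_row("A_1", "B_1", evalue = 1e-5)), 1L)   # inclusive
  expect_equal(keep(hit_row("A_1", "B_1", evalue = 2e-5)), 0L)
  # coverage of BOTH lengths: aln 59 on lengths 100/80 fails (59 < 60)
  expect_equal(keep(hit_row("A_1", "B_1", len = 59, qlen = 100, slen = 80)), 0L)
  expect_equal(keep(hit_row("A_1", "B_1", len = 60, qlen = 100, slen = 80)), 1L)
  # self-hits are dropped
  expect_equal(keep(hit_row("A_1", "A_1")), 0L)
})

test_that("reciprocal duplicates collapse to one pair keeping the best record", {
  gm <- toy_map(c("A_1", "B_1"))
  h <- rbind(hit_row("A_1", "B_1", bitscore = 200),
             hit_row("B_1", "A_1", bitscore = 210))
  p <- filter_homologs(annotate_genomes(h, gm))
  expect_equal(nrow(p), 1L)
  expect_equal(p$bitscore, 210)
  expect_equal(p$gene_a, "A_1")  # unordered, lexicographically stored
})

test_that("BBH requires reciprocity and is row-order invariant", {
  gm <- toy_map(c("A_1", "A_2", "B_1"))
  h <- rbind(hit_row("A_1", "B_1", bitscore = 300),
             hit_row("B_1", "A_2", bitscore = 400),
             hit_row("A_2", "B_1", bitscore = 400))
  p <- filter_homologs(annotate_genomes(h, gm))
  bb <- bidirectional_best_hits(p, "A", "B")
  expect_equal(nrow(bb), 1L)
  expect_equal(bb$gene_a, "A_2")  # A_1 -> B_1 best, but B_1 -> A_2 best
  # swapping presentation and shuffling rows changes nothing
  h2 <- h[c(3, 1, 2), ]
  tmp <- h2$qseqid; h2$qseqid <- h2$sseqid; h2$sseqid <- tmp
  tmp <- h2$qlen; h2$qlen <- h2$slen; h2$slen <- tmp
  bb2 <- bidirectional_best_hits(filter_homologs(annotate_genomes(h2, gm)),
                                 "A", "B")
  expect_identical(bb, bb2)
})

test_that("BBH matches the exhaustive reciprocal-best oracle", {
  withr::local_seed(42)
  for (rep in 1:10) {
    ids_a <- paste0("A_", 1:5)
    ids_b <- paste0("B_", 1:5)
    gm <- toy_map(c(ids_a, ids_b))
    rows <- list()
    for (q in ids_a) for (s in sample(ids_b, sample(2:5, 1))) {
      rows[[length(rows) + 1L]] <-
        hit_row(q, s, bitscore = sample(100:500, 1),
                evalue = 10^-sample(10:80, 1), pident = runif(1, 40, 99))
    }
    p <- filter_homologs(annotate_genomes(do.call(rbind, rows), gm))
    got <- bidirectional_best_hits(p, "A", "B")
    want <- oracle_bbh(p, "A", "B")
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(Map(c, got$gene_a, got$gene_b), setNames(want,
                   vapply(want, `[`, character(1), 1)), ignore_attr = TRUE)
    }
  }
})

test_that("single-linkage families equal the brute-force transitive closure", {
  pairs <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))
  fam <- single_linkage_families(pairs)
  expect_equal(unique(fam$families$family_id), 1L)
  expect_equal(sort(fam$families$gene_id), c("A", "B", "C"))

  pairs2 <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"))
  fam2 <- single_linkage_families(pairs2)
  expect_equal(max(fam2$families$family_id), 2L)

  withr::local_seed(99)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:20)
    n_edges <- sample(5:25, 1)
    e <- data.frame(gene_a = sample(genes, n_edges, replace = TRUE),
                    gene_b = sample(genes, n_edges, replace = TRUE))
    e <- e[e$gene_a != e$gene_b, ]
    got <- single_linkage_families(e)
    want <- oracle_closure(e)
    want <- want[lengths(want) >= 2]
    want <- want[order(vapply(want, `[`, character(1), 1))]
    got_sets <- split(got$families$gene_id, got$families$family_id)
    expect_equal(unname(got_sets), want, ignore_attr = TRUE)
    # invariant to pair order and duplication
    e2 <- rbind(e[sample(nrow(e)), ], e)
    expect_identical(single_linkage_families(e2)$families, got$families)
  }
})

test_that("seed expansion returns the union of touched components", {
  pairs <- data.frame(gene_a = c("A", "B", "X"), gene_b = c("B", "C", "Y"))
  expect_equal(expand_family_by_linkage("A", pairs), c("A", "B", "C"))
  expect_equal(expand_family_by_linkage("Z", pairs,
                                        universe = c("Z", "A", "B", "C")), "Z")
  expect_equal(expand_family_by_linkage(c("A", "X"), pairs),
               c("A", "B", "C", "X", "Y"))
  expect_error(expand_family_by_linkage("missing", pairs,
                                        universe = c("A", "B")), "missing")
})

test_that("four-way classification recovers planted presence patterns", {
  sim <- simulate_hit_table(
    genome_groups = c(ao = "focal", p1 = "pathogen", p2 = "pathogen",
                      n1 = "nonpathogen", n2 = "nonpathogen"),
    n_per_category = c(specific = 10, with_pathogen = 10,
                       shared_both_groups = 10, with_nonpathogen = 10),
    n_families = 0, family_size = 0, n_decoys = 9, seed = 7)
  p <- filter_homologs(sim$hits)
  bb <- bbh_all_pairs(p)
  got <- classify_categories(sim$focal_genes, bb,
                             c(ao = "focal", p1 = "pathogen", p2 = "pathogen",
                               n1 = "nonpathogen", n2 = "nonpathogen"))
  want <- sim$truth$categories
  expect_equal(got[order(got$gene_id), ]$category,
               want[order(want$gene_id), ]$category)
  # partition identity: category counts sum to focal proteome size
  expect_equal(sum(table(got$category)), length(sim$focal_genes))
})

test_that("classification edge cases follow the definitions", {
  bb <- data.frame(gene_a = c("f1", "f1", "f2"),
                   gene_b = c("pA_1", "pB_1", "nA_1"),
                   genome_a = "focal", genome_b = c("pA", "pB", "nA"))
  groups <- c(focal = "focal", pA = "pathogen", pB = "pathogen",
              nA = "nonpathogen")
  got <- classify_categories(c("f1", "f2", "f3"), bb, groups)
  expect_equal(got$category, c("with_pathogen", "with_nonpathogen", "specific"))
  expect_error(classify_categories("f1", bb, c(focal = "focal", pA = "pathogen")),
               "nonpathogen")
  expect_error(classify_categories("f1", bb,
                                   c(pA = "pathogen", nA = "nonpathogen")),
               "focal")
})

test_that("reference annotation reports each gene's best surviving hit", {
  gm <- data.frame(gene_id = c("f_1", "f_2", "ref_1", "ref_2"),
                   genome = c("focal", "focal", "ref", "ref"))
  h <- rbind(hit_row("f_1", "ref_1", bitscore = 100),
             hit_row("f_1", "ref_2", bitscore = 300),
             hit_row("f_2", "ref_1", pident = 10))  # fails identity filter
  ann <- annotate_by_reference(annotate_genomes(h, gm), "focal", "ref")
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$gene_id, "f_1")
  expect_equal(ann$reference_id, "ref_2")
})

test_that("planted orthologs are recovered perfectly; decoys never pass", {
  sim <- simulate_hit_table(
    genome_groups = c(ao = "focal", p1 = "pathogen", n1 = "nonpathogen"),
    n_per_category = c(specific = 5, with_pathogen = 5,
                       shared_both_groups = 5, with_nonpathogen = 5),
    n_families = 3, family_size = 4, n_decoys = 12, seed = 21)
  p <- filter_homologs(sim$hits)
  # decoys each violate one filter, so no decoy row survives:
  # every surviving pair is a planted one
  planted_cross <- sum(vapply(
    c("with_pathogen", "shared_both_groups", "with_nonpathogen"),
    function(cc) {
      k <- sum(sim$truth$categories$category == cc &
                 !grepl("fam", sim$truth$categories$gene_id))
      m <- switch(cc, with_pathogen = 1, with_nonpathogen = 1,
                  shared_both_groups = 2)
      k * choose(m + 1, 2)
    }, numeric(1)))
  planted_fam <- 3 * (4 - 1)
  expect_equal(nrow(p), planted_cross + planted_fam)
  fam <- single_linkage_families(p[p$genome_a == "ao" & p$genome_b == "ao", ])
  expect_equal(length(unique(fam$families$family_id)), 3L)
  got_sets <- unname(split(fam$families$gene_id, fam$families$family_id))
  expect_equal(got_sets, lapply(sim$truth$families, sort))
})
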