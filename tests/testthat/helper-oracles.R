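# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the slowest, most literal formulation of each rule.

# character-by-character dinucleotide counting and index computation
oracle_rip <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  counts <- setNames(rep(0L, 16),
                     as.vector(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"), paste0)))
  for (i in seq_len(max(0L, n - 1L))) {
    pair <- substr(s, i, i + 1L)
    if (!grepl("N", pair, fixed = TRUE)) {
      counts[pair] <- counts[pair] + 1L
    }
  }
  nb <- function(b) lengths(regmatches(s, gregexpr(b, s, fixed = TRUE)))
  a <- nb("A"); c_ <- nb("C"); g <- nb("G"); t_ <- nb("T")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(counts = counts, valid_pairs = sum(counts),
       product_index = ratio(counts[["TA"]], counts[["AT"]]),
       substrate_index = ratio(counts[["CA"]] + counts[["TG"]],
                               counts[["AC"]] + counts[["GT"]]),
       at_content = if (a + c_ + g + t_ == 0) NA_real_
                    else (a + t_) / (a + c_ + g + t_))
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

random_test_seq <- function(len, gc = 0.5, n_frac = 0) {
  p <- c(A = (1 - gc) / 2 * (1 - n_frac), C = gc / 2 * (1 - n_frac),
         G = gc / 2 * (1 - n_frac), T = (1 - gc) / 2 * (1 - n_frac),
         N = n_frac)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# literal transitive closure by repeated expansion (no graph library)
oracle_closure <- function(pairs) {
  sets <- lapply(unique(c(pairs$gene_a, pairs$gene_b)), function(g) g)
  edges <- Map(c, pairs$gene_a, pairs$gene_b)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (e in edges) {
      i <- which(vapply(sets, function(s) e[1] %in% s, logical(1)))
      j <- which(vapply(sets, function(s) e[2] %in% s, logical(1)))
      if (i != j) {
        sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
        sets[[j]] <- NULL
        changed <- TRUE
      }
    }
  }
  lapply(sets, sort)
}

# exhaustive reciprocal-best search over a directed hit list
oracle_bbh <- function(pairs, gx, gy) {
  d <- rbind(
    data.frame(gene = pairs$gene_a, genome = pairs$genome_a,
               partner = pairs$gene_b, pg = pairs$genome_b,
               bitscore = pairs$bitscore, evalue = pairs$evalue,
               pident = pairs$pident),
    data.frame(gene = pairs$gene_b, genome = pairs$genome_b,
               partner = pairs$gene_a, pg = pairs$genome_a,
               bitscore = pairs$bitscore, evalue = pairs$evalue,
               pident = pairs$pident))
  best <- function(gene, to) {
    cand <- d[d$gene == gene & d$pg == to, ]
    if (nrow(cand) == 0) return(NA_character_)
    cand <- cand[order(-cand$bitscore, cand$evalue, -cand$pident,
                       cand$partner), ]
    cand$partner[1]
  }
  xs <- sort(unique(d$gene[d$genome == gx & d$pg == gy]))
  out <- list()
  for (x in xs) {
    b <- best(x, gy)
    if (!is.na(b) && identical(best(b, gx), x)) {
      out[[length(out) + 1L]] <- c(x, b)
    }
  }
  out
}

# distance matrix read off a random tree (additive by construction)
additive_matrix <- function(ntaxa, seed) {
  withr::with_seed(seed, {
    tree <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.1, 2))
  })
  tree$tip.label <- sort(tree$tip.label)  # labels t1..tn in fixed order
  list(tree = ape::unroot(tree), D = ape::cophenetic.phylo(tree))
}

expect_same_topology <- function(t1, t2) {
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
}
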