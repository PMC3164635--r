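# Concatenated single-copy-ortholog phylogenomics: universal ortholog group
# selection from BBHs, supermatrix concatenation of pre-aligned groups,
# p-distances with pairwise gap deletion, and neighbor-joining.

#' Universal single-copy ortholog groups
#'
#' Groups genes such that every genome contributes exactly one member and
#' every pair of members is a BBH in its genome pair (the clique criterion;
#' stricter than connected components, guarding against paralog chaining).
#' With `clique = FALSE` the relaxed criterion is used instead: connected
#' components of the BBH graph containing exactly one gene per genome.
#'
#' @param bbhs BBH table over all genome pairs (see [bbh_all_pairs()]).
#' @param genomes Character vector of all genome labels.
#' @param clique Require the full BBH clique (default) or fall back to
#'   one-per-genome connected components.
#' @return data.frame group_id, genome, gene_id (long format).
#' @export
universal_single_copy_groups <- function(bbhs, genomes, clique = TRUE) {
  genomes <- sort(genomes)
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  empty <- data.frame(group_id = integer(), genome = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (nrow(bbhs) == 0L) return(empty)
  d <- rbind(
    data.frame(gene = bbhs$gene_a, genome = bbhs$genome_a,
               partner = bbhs$gene_b, partner_genome = bbhs$genome_b,
               stringsAsFactors = FALSE),
    data.frame(gene = bbhs$gene_b, genome = bbhs$genome_b,
               partner = bbhs$gene_a, partner_genome = bbhs$genome_a,
               stringsAsFactors = FALSE))
  # a gene has at most one BBH partner per other genome by construction
  partner_of <- stats::setNames(d$partner, paste(d$gene, d$partner_genome))
  is_bbh <- paste(pmin(d$gene, d$partner), pmax(d$gene, d$partner))

  groups <- list()
  if (clique) {
    g1 <- genomes[1]
    others <- genomes[-1]
    anchors <- sort(unique(d$gene[d$genome == g1]))
    for (x in anchors) {
      members <- stats::setNames(
        partner_of[paste(x, others)], others)
      if (anyNA(members)) next
      members <- c(stats::setNames(x, g1), members)
      pairs_needed <- utils::combn(unname(members), 2)
      keys <- paste(pmin(pairs_needed[1, ], pairs_needed[2, ]),
                    pmax(pairs_needed[1, ], pairs_needed[2, ]))
      if (all(keys %in% is_bbh)) groups[[length(groups) + 1L]] <- members
    }
  } else {
    g <- igraph::graph_from_data_frame(
      unique(data.frame(a = bbhs$gene_a, b = bbhs$gene_b)), directed = FALSE)
    comp <- igraph::components(g)
    genome_of <- stats::setNames(d$genome, d$gene)
    for (m in split(names(comp$membership), comp$membership)) {
      gs <- genome_of[m]
      if (length(m) == length(genomes) && setequal(gs, genomes)) {
        groups[[length(groups) + 1L]] <- stats::setNames(m, gs)[genomes]
      }
    }
    groups <- groups[order(vapply(groups, `[[`, character(1), 1L))]
  }
  if (length(groups) == 0L) return(empty)
  data.frame(group_id = rep(seq_along(groups), each = length(genomes)),
             genome = rep(genomes, times = length(groups)),
             gene_id = unlist(lapply(groups, `[`, genomes),
                              use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Read one aligned FASTA (rows keyed by genome label)
#'
#' @param path Aligned protein FASTA.
#' @return Named character vector of aligned rows.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

#' Concatenate per-group alignments into a supermatrix
#'
#' Groups are concatenated in sorted order of their names; every group must
#' contain every genome exactly once and be rectangular.
#'
#' @param alignments Named list; each element a named character vector of
#'   equal-length aligned rows keyed by genome label.
#' @return List of class `supermatrix`: `seqs` (named character vector of
#'   concatenated rows) and `boundaries` (data.frame group_id, start, end;
#'   0-based half-open column spans).
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  ord <- sort(names(alignments))
  taxa <- sort(unique(unlist(lapply(alignments, names))))
  pos <- 0L
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  bounds <- list()
  for (gid in ord) {
    aln <- alignments[[gid]]
    missing <- setdiff(taxa, names(aln))
    extra <- setdiff(names(aln), taxa)
    if (length(missing) || length(extra) || anyDuplicated(names(aln))) {
      stop("group ", gid, ": taxa mismatch",
           if (length(missing)) paste0(" (missing: ",
                                       paste(missing, collapse = ", "), ")"))
    }
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L) stop("group ", gid, ": ragged alignment")
    rows <- paste0(rows, aln[taxa])
    names(rows) <- taxa
    bounds[[length(bounds) + 1L]] <- data.frame(
      group_id = gid, start = pos, end = pos + lens[[1]])
    pos <- pos + lens[[1]]
  }
  structure(list(seqs = rows, boundaries = do.call(rbind, bounds)),
            class = "supermatrix")
}

# residues regarded as missing for distance purposes
.P_DIST_MISSING <- c("-", ".", "?", "X", "*", "B", "Z", "J")

#' Pairwise p-distance matrix over a supermatrix
#'
#' d(i, j) = mismatches / compared columns. Columns with a gap or ambiguity
#' code in either row are excluded for that pair (pairwise deletion; set
#' `deletion = "complete"` to drop such columns globally).
#'
#' @param x A `supermatrix` or a named character vector of equal-length rows.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Square symmetric numeric matrix with taxa dimnames.
#' @export
p_distance_matrix <- function(x, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  seqs <- if (inherits(x, "supermatrix")) x$seqs else x
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L) stop("rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  valid <- !matrix(mat %in% .P_DIST_MISSING, nrow = nrow(mat))
  if (deletion == "complete") {
    keep <- apply(valid, 2, all)
    mat <- mat[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      both <- valid[i, ] & valid[j, ]
      nc <- sum(both)
      if (nc == 0L) stop("no comparable columns between ",
                         rownames(mat)[i], " and ", rownames(mat)[j])
      D[i, j] <- D[j, i] <- sum(mat[i, both] != mat[j, both]) / nc
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration on the Q-criterion with deterministic tie-breaking
#' (the candidate pair whose sorted representative labels — the smallest leaf
#' label under each node — are lexicographically smallest). Branch lengths
#' come from the standard two-point formulas; negative estimates are clamped
#' to zero with a warning.
#'
#' @param D Square symmetric non-negative matrix with zero diagonal and taxa
#'   dimnames; >= 3 taxa.
#' @return An [ape::read.tree()] `phylo` object (unrooted for >= 3 taxa).
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) stop("distance matrix needs taxa dimnames")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("negative distances")
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.17g", x)
  labels <- rownames(D)
  nwk <- stats::setNames(labels, labels)   # subtree newick per active node
  rep_label <- stats::setNames(labels, labels)  # min leaf label under node
  act <- labels
  Dm <- D
  next_id <- 0L
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      rl <- sort(c(rep_label[act[ij[1]]], rep_label[act[ij[2]]]))
      paste(rl, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- act[pick[1]]; j <- act[pick[2]]
    dij <- Dm[i, j]
    li <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    next_id <- next_id + 1L
    u <- paste0(".n", next_id)
    others <- setdiff(act, c(i, j))
    du <- (Dm[i, others] + Dm[j, others] - dij) / 2
    Dm <- Dm[others, others, drop = FALSE]
    Dm <- rbind(cbind(Dm, `u` = du), `u` = c(du, 0))
    rownames(Dm)[nrow(Dm)] <- u
    colnames(Dm)[ncol(Dm)] <- u
    nwk[u] <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    rep_label[u] <- min(rep_label[i], rep_label[j])
    act <- c(others, u)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- clamp((Dm[a, b] + Dm[a, c3] - Dm[b, c3]) / 2)
  lb <- clamp((Dm[a, b] + Dm[b, c3] - Dm[a, c3]) / 2)
  lc <- clamp((Dm[a, c3] + Dm[b, c3] - Dm[a, b]) / 2)
  txt <- paste0("(", nwk[a], ":", fmt(la), ",", nwk[b], ":", fmt(lb), ",",
                nwk[c3], ":", fmt(lc), ");")
  if (clamped) warning("negative branch length estimate(s) clamped to 0")
  ape::read.tree(text = txt)
}

#' Write/read a square PHYLIP distance matrix
#'
#' @param D Square matrix with taxa dimnames.
#' @param path File path.
#' @return `path` invisibly (write); matrix (read).
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(rownames(D)[i], sprintf("%.10f", D[i, ])),
                     collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  taxa <- vapply(parts, `[`, character(1), 1L)
  D <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(D) <- list(taxa, taxa)
  D
}
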