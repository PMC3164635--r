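# All-vs-all protein homology: filtering, bidirectional best hits (BBH),
# single-linkage transitive-closure families, four-way genome-category
# classification, and best-hit annotation against a reference protein set.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "qlen", "slen")

#' Read an all-vs-all hit table (tabular search output + sequence lengths)
#'
#' Expects the standard 12-column tabular search format extended with two
#' columns `qlen` and `slen`; alternatively the 12-column form plus a separate
#' named vector of protein lengths.
#'
#' @param path Path to a tab-separated hit table without header.
#' @param genome_map Named character vector or two-column data.frame
#'   (`gene_id`, `genome`) mapping every protein id to its genome label.
#' @param lengths Optional named numeric vector of protein lengths, required
#'   when the table has only 12 columns.
#' @return data.frame with the 14 standard columns plus `query_genome` and
#'   `subject_genome`.
#' @export
read_hit_table <- function(path, genome_map, lengths = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "#")
  if (ncol(df) == 12L) {
    if (is.null(lengths)) {
      stop("hit table has no qlen/slen columns; supply protein lengths ",
           "via the `lengths` argument")
    }
    df$qlen <- unname(lengths[df[[1]]])
    df$slen <- unname(lengths[df[[2]]])
    if (anyNA(df$qlen) || anyNA(df$slen)) {
      missing <- unique(c(df[[1]][is.na(df$qlen)], df[[2]][is.na(df$slen)]))
      stop("no length for protein id(s): ", paste(missing, collapse = ", "))
    }
  } else if (ncol(df) != 14L) {
    stop("expected 12 or 14 tab-separated columns, found ", ncol(df))
  }
  names(df) <- HIT_COLUMNS
  bad <- !stats::complete.cases(df[, c("pident", "length", "evalue",
                                       "bitscore", "qlen", "slen")])
  if (any(bad)) stop("malformed hit table row(s): line ",
                     paste(which(bad), collapse = ", "))
  annotate_genomes(df, genome_map)
}

#' Attach genome labels to a hit table
#'
#' @param hits Hit data.frame with at least `qseqid` and `sseqid`.
#' @param genome_map Named character vector or data.frame (`gene_id`,
#'   `genome`).
#' @return `hits` with `query_genome` and `subject_genome` columns.
#' @export
annotate_genomes <- function(hits, genome_map) {
  if (is.data.frame(genome_map)) {
    genome_map <- stats::setNames(as.character(genome_map[[2]]),
                                  genome_map[[1]])
  }
  qg <- unname(genome_map[hits$qseqid])
  sg <- unname(genome_map[hits$sseqid])
  if (anyNA(qg) || anyNA(sg)) {
    missing <- unique(c(hits$qseqid[is.na(qg)], hits$sseqid[is.na(sg)]))
    stop("protein id(s) absent from genome map: ",
         paste(missing, collapse = ", "))
  }
  hits$query_genome <- qg
  hits$subject_genome <- sg
  hits
}

#' Default homology filter
#'
#' Hits are homologous when E-value <= 1e-5, identity >= 30% and the
#' alignment covers >= 60% of BOTH protein lengths (inclusive bounds;
#' alignment length as reported, gap columns included).
#'
#' @param max_evalue,min_identity_pct,min_coverage_fraction Thresholds.
#' @return Named list of validated thresholds.
#' @export
homology_filter <- function(max_evalue = 1e-5, min_identity_pct = 30,
                            min_coverage_fraction = 0.6) {
  stopifnot(max_evalue > 0, min_identity_pct >= 0,
            min_coverage_fraction > 0, min_coverage_fraction <= 1)
  list(max_evalue = max_evalue, min_identity_pct = min_identity_pct,
       min_coverage_fraction = min_coverage_fraction)
}

# deterministic hit ordering: best first
.order_hits <- function(df, partner) {
  order(-df$bitscore, df$evalue, -df$pident, df[[partner]])
}

#' Filter hits to homologous pairs
#'
#' Applies the E-value/identity/two-sided-coverage filter, drops self-hits,
#' and collapses reciprocal duplicates of the same alignment to one unordered
#' pair keeping the best-scoring record.
#'
#' @param hits Hit table with genome labels (see [read_hit_table()]).
#' @param filter Thresholds from [homology_filter()].
#' @return data.frame of unordered pairs: gene_a, gene_b (gene_a < gene_b),
#'   genome_a, genome_b, pident, length, evalue, bitscore.
#' @export
filter_homologs <- function(hits, filter = homology_filter()) {
  cov <- filter$min_coverage_fraction
  keep <- hits$evalue <= filter$max_evalue &
    hits$pident >= filter$min_identity_pct &
    hits$length >= cov * hits$qlen &
    hits$length >= cov * hits$slen &
    hits$qseqid != hits$sseqid
  df <- hits[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      genome_a = character(), genome_b = character(),
                      pident = numeric(), length = numeric(),
                      evalue = numeric(), bitscore = numeric()))
  }
  flip <- df$sseqid < df$qseqid
  pairs <- data.frame(
    gene_a = ifelse(flip, df$sseqid, df$qseqid),
    gene_b = ifelse(flip, df$qseqid, df$sseqid),
    genome_a = ifelse(flip, df$subject_genome, df$query_genome),
    genome_b = ifelse(flip, df$query_genome, df$subject_genome),
    pident = df$pident, length = df$length,
    evalue = df$evalue, bitscore = df$bitscore,
    stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$bitscore, pairs$evalue, -pairs$pident,
                       pairs$gene_a, pairs$gene_b), , drop = FALSE]
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# long (directed) view of an unordered pair table: one row per direction
.directed_pairs <- function(pairs) {
  rbind(
    data.frame(gene = pairs$gene_a, partner = pairs$gene_b,
               genome = pairs$genome_a, partner_genome = pairs$genome_b,
               pident = pairs$pident, evalue = pairs$evalue,
               bitscore = pairs$bitscore, stringsAsFactors = FALSE),
    data.frame(gene = pairs$gene_b, partner = pairs$gene_a,
               genome = pairs$genome_b, partner_genome = pairs$genome_a,
               pident = pairs$pident, evalue = pairs$evalue,
               bitscore = pairs$bitscore, stringsAsFactors = FALSE))
}

.empty_bbh <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             genome_a = character(), genome_b = character(),
             stringsAsFactors = FALSE)
}

#' Bidirectional best hits between two genomes
#'
#' A pair (a, b) is a BBH when b is a's best-scoring homolog in genome B and
#' a is b's best in genome A. "Best" is max bitscore, ties broken by lower
#' E-value, then higher identity, then lexicographically smaller partner id,
#' so output is invariant to input row order.
#'
#' @param pairs Filtered unordered pairs from [filter_homologs()].
#' @param genome_x,genome_y Two distinct genome labels.
#' @return data.frame gene_a/gene_b/genome_a/genome_b with gene_a from
#'   `genome_x`.
#' @export
bidirectional_best_hits <- function(pairs, genome_x, genome_y) {
  stopifnot(genome_x != genome_y)
  d <- .directed_pairs(pairs)
  d <- d[d$genome == genome_x & d$partner_genome == genome_y, , drop = FALSE]
  if (nrow(d) == 0L) return(.empty_bbh())
  d <- d[order(-d$bitscore, d$evalue, -d$pident, d$partner), , drop = FALSE]
  best_xy <- d[!duplicated(d$gene), c("gene", "partner")]
  best_yx <- stats::setNames(best_xy$gene, best_xy$partner)
  # reciprocal: partner's best must be the gene itself; recompute from y side
  dy <- .directed_pairs(pairs)
  dy <- dy[dy$genome == genome_y & dy$partner_genome == genome_x, , drop = FALSE]
  dy <- dy[order(-dy$bitscore, dy$evalue, -dy$pident, dy$partner), , drop = FALSE]
  best_y <- stats::setNames(dy$partner[!duplicated(dy$gene)],
                            dy$gene[!duplicated(dy$gene)])
  mutual <- best_y[best_xy$partner] == best_xy$gene
  keep <- best_xy[!is.na(mutual) & mutual, , drop = FALSE]
  out <- data.frame(gene_a = keep$gene, gene_b = keep$partner,
                    genome_a = genome_x, genome_b = genome_y,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' BBHs for every genome pair
#'
#' @param pairs Filtered unordered pairs.
#' @param genomes Character vector of genome labels (defaults to all labels
#'   present).
#' @return Row-bound BBH table over all unordered genome pairs, with
#'   genome_a < genome_b.
#' @export
bbh_all_pairs <- function(pairs, genomes = NULL) {
  if (is.null(genomes)) {
    genomes <- sort(unique(c(pairs$genome_a, pairs$genome_b)))
  }
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  out <- list()
  gs <- sort(genomes)
  for (i in seq_along(gs)[-length(gs)]) {
    for (j in seq((i + 1L), length(gs))) {
      out[[length(out) + 1L]] <- bidirectional_best_hits(pairs, gs[i], gs[j])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-linkage transitive-closure families
#'
#' Families are the connected components of the pairwise-homology graph;
#' components with >= 2 members become families with ids assigned in order of
#' their smallest member id. Singletons are not families but are reported.
#'
#' @param pairs Unordered pair table (only gene_a/gene_b used).
#' @param universe Optional character vector of all gene ids; genes absent
#'   from `pairs` then appear as singletons.
#' @return List with `families` (data.frame family_id, gene_id) and
#'   `singletons` (character vector).
#' @export
single_linkage_families <- function(pairs, universe = NULL) {
  edges <- unique(data.frame(a = pairs$gene_a, b = pairs$gene_b,
                             stringsAsFactors = FALSE))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  verts <- sort(unique(c(edges$a, edges$b, universe)))
  if (length(verts) == 0L) {
    return(list(families = data.frame(family_id = integer(),
                                      gene_id = character()),
                singletons = character()))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  sizes <- lengths(members)
  fams <- members[sizes >= 2L]
  fams <- fams[order(vapply(fams, `[`, character(1), 1L))]
  families <- if (length(fams)) {
    data.frame(family_id = rep(seq_along(fams), lengths(fams)),
               gene_id = unlist(fams, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(family_id = integer(), gene_id = character())
  }
  list(families = families,
       singletons = sort(unlist(members[sizes == 1L], use.names = FALSE)))
}

#' Expand a seed gene set by single-linkage closure
#'
#' Returns the union of the connected components containing any seed id
#' (a seed with no homologous pair stays a singleton).
#'
#' @param seeds Seed gene ids.
#' @param pairs Unordered pair table.
#' @param universe Optional set of known gene ids; seeds outside it are an
#'   error. Defaults to seeds plus all genes in `pairs`.
#' @return Sorted character vector of the expanded gene set.
#' @export
expand_family_by_linkage <- function(seeds, pairs, universe = NULL) {
  all_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  if (is.null(universe)) universe <- unique(c(seeds, all_genes))
  unknown <- setdiff(seeds, universe)
  if (length(unknown)) stop("unknown seed id(s): ",
                            paste(unknown, collapse = ", "))
  fam <- single_linkage_families(pairs, universe = universe)
  comp <- rbind(fam$families[, c("family_id", "gene_id")],
                data.frame(family_id = -seq_along(fam$singletons),
                           gene_id = fam$singletons))
  hit_fams <- unique(comp$family_id[comp$gene_id %in% seeds])
  sort(unique(c(seeds, comp$gene_id[comp$family_id %in% hit_fams])))
}

#' Classify focal-genome genes into four sharing categories
#'
#' Each focal gene is categorized by where it has BBH orthologs:
#' `specific` (nowhere else), `with_pathogen` (>= 1 pathogen genome only),
#' `with_nonpathogen` (>= 1 non-pathogen genome only), or
#' `shared_both_groups` (>= 1 of each). The four counts always partition the
#' focal proteome.
#'
#' @param focal_genes Character vector: the full focal proteome.
#' @param bbhs BBH table (rows from [bidirectional_best_hits()] /
#'   [bbh_all_pairs()]) covering at least every (focal, other) genome pair.
#' @param groups Named character vector genome -> group, with exactly one
#'   `"focal"` and at least one `"pathogen"` and one `"nonpathogen"`.
#' @return data.frame gene_id, category.
#' @export
classify_categories <- function(focal_genes, bbhs, groups) {
  focal <- names(groups)[groups == "focal"]
  if (length(focal) != 1L) stop("groups must name exactly one focal genome")
  if (!any(groups == "pathogen") || !any(groups == "nonpathogen")) {
    stop("groups must contain at least one pathogen and one nonpathogen genome")
  }
  d <- rbind(
    data.frame(gene = bbhs$gene_a, genome = bbhs$genome_a,
               partner_genome = bbhs$genome_b, stringsAsFactors = FALSE),
    data.frame(gene = bbhs$gene_b, genome = bbhs$genome_b,
               partner_genome = bbhs$genome_a, stringsAsFactors = FALSE))
  d <- d[d$genome == focal, , drop = FALSE]
  grp <- groups[d$partner_genome]
  has_p <- focal_genes %in% d$gene[!is.na(grp) & grp == "pathogen"]
  has_n <- focal_genes %in% d$gene[!is.na(grp) & grp == "nonpathogen"]
  category <- ifelse(has_p & has_n, "shared_both_groups",
              ifelse(has_p, "with_pathogen",
              ifelse(has_n, "with_nonpathogen", "specific")))
  data.frame(gene_id = focal_genes, category = category,
             stringsAsFactors = FALSE)
}

#' Annotate focal proteins by their best reference hit
#'
#' Generic best-hit annotation against a reference protein set (e.g. a
#' pathogen-host-interaction gene database): each focal gene with at least
#' one hit surviving the homology filter is reported once with its
#' best-scoring reference match.
#'
#' @param hits Directed hit table (focal queries vs reference subjects) with
#'   genome labels.
#' @param focal_genome,reference_genome Genome labels selecting the
#'   direction.
#' @param filter Thresholds from [homology_filter()].
#' @return data.frame gene_id, reference_id, pident, evalue, bitscore.
#' @export
annotate_by_reference <- function(hits, focal_genome, reference_genome,
                                  filter = homology_filter()) {
  cov <- filter$min_coverage_fraction
  keep <- hits$query_genome == focal_genome &
    hits$subject_genome == reference_genome &
    hits$evalue <= filter$max_evalue &
    hits$pident >= filter$min_identity_pct &
    hits$length >= cov * hits$qlen &
    hits$length >= cov * hits$slen
  d <- hits[keep, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(gene_id = character(), reference_id = character(),
                      pident = numeric(), evalue = numeric(),
                      bitscore = numeric()))
  }
  d <- d[.order_hits(d, "sseqid"), , drop = FALSE]
  d <- d[!duplicated(d$qseqid), , drop = FALSE]
  out <- data.frame(gene_id = d$qseqid, reference_id = d$sseqid,
                    pident = d$pident, evalue = d$evalue,
                    bitscore = d$bitscore, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
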