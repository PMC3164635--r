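# Synthetic-data generators: every pipeline input with known ground truth.
# All generators are pure functions of their arguments plus a mandatory seed
# (no silent nondeterminism).

#' Random genome of chosen GC content
#'
#' Residues are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#'
#' @param length Genome length in bp.
#' @param gc_fraction GC fraction in (0, 1).
#' @param seed Integer seed (mandatory).
#' @return A single character string.
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed) {
  stopifnot(length >= 0, gc_fraction > 0, gc_fraction < 1)
  if (length == 0) return("")
  withr::with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Plant identical repeat copies into a genome
#'
#' One random master sequence is written over `copies` non-overlapping
#' positions; before mutagenesis all copies are identical.
#'
#' @param genome Genome sequence (single string).
#' @param repeat_length Length of the repeat unit in bp.
#' @param copies Number of copies.
#' @param seed Integer seed.
#' @param gc_fraction GC content of the repeat master.
#' @return List: `genome` (modified sequence) and `repeats` (interval
#'   data.frame of the planted copies, contig id `"genome"`).
#' @export
plant_repeats <- function(genome, repeat_length, copies, seed,
                          gc_fraction = 0.5) {
  L <- nchar(genome)
  if (copies == 0L) {
    return(list(genome = genome, repeats = intervals()))
  }
  if (copies * repeat_length >= L) {
    stop("cannot pack ", copies, " x ", repeat_length,
         " bp repeats into ", L, " bp")
  }
  withr::with_seed(seed, {
    master <- paste(sample(c("A", "C", "G", "T"), repeat_length,
                           replace = TRUE,
                           prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                                    gc_fraction / 2, (1 - gc_fraction) / 2)),
                    collapse = "")
    # slack-placement trick guarantees non-overlap deterministically
    slack <- L - copies * repeat_length
    offs <- sort(sample.int(slack + 1L, copies, replace = TRUE) - 1L)
    starts <- offs + (seq_len(copies) - 1L) * repeat_length
  })
  g <- genome
  for (s in starts) substr(g, s + 1L, s + repeat_length) <- master
  list(genome = g,
       repeats = intervals(contig = rep("genome", copies),
                           start = starts, end = starts + repeat_length))
}

#' Apply RIP-style mutation within target intervals
#'
#' Within the targets, each forward-strand CpA site has its C replaced by T
#' with probability `rate`, and each forward-strand TpG site (a CpA on the
#' reverse strand) has its G replaced by A with probability `rate`. Sites are
#' evaluated against the pre-mutation sequence in a single pass, so
#' overlapping contexts do not cascade; bases outside the targets are never
#' touched, and A/T residues are never changed.
#'
#' @param seq Contig sequence.
#' @param targets Interval data.frame (0-based half-open; contig ignored).
#' @param rate Per-site mutation probability in [0, 1].
#' @param seed Integer seed.
#' @return Mutated sequence (single string).
#' @export
simulate_rip <- function(seq, targets, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  s <- normalize_seq(seq)
  n <- nchar(s)
  if (n < 2L || nrow(targets) == 0L || rate == 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  in_target <- rep(FALSE, n)
  for (k in seq_len(nrow(targets))) {
    if (targets$end[k] > n) stop("target interval beyond sequence end")
    in_target[(targets$start[k] + 1L):targets$end[k]] <- TRUE
  }
  left <- chars[-n]; right <- chars[-1L]
  # a dinucleotide site counts as inside iff both its bases are inside
  pair_in <- in_target[-n] & in_target[-1L]
  ca <- which(left == "C" & right == "A" & pair_in)     # mutate the C (pos i)
  tg <- which(left == "T" & right == "G" & pair_in) + 1L # mutate the G (pos i+1)
  withr::with_seed(seed, {
    hit_ca <- ca[stats::runif(length(ca)) < rate]
    hit_tg <- tg[stats::runif(length(tg)) < rate]
  })
  chars[hit_ca] <- "T"
  chars[hit_tg] <- "A"
  paste(chars, collapse = "")
}

#' Simulate an all-vs-all hit table with planted structure
#'
#' Builds proteomes for a focal genome plus pathogen/non-pathogen genomes,
#' plants ortholog sets with known presence patterns (driving the four-way
#' category classification and universal single-copy group selection),
#' plants single-linkage families as pair chains within the focal proteome,
#' and emits decoy hits that each violate exactly one homology filter
#' (E-value, identity, or coverage), to exercise each filter branch.
#'
#' Planted cross-genome hits have identity/coverage far above the default
#' thresholds and are emitted in both orientations.
#'
#' @param genome_groups Named character vector genome -> group
#'   (`focal`/`pathogen`/`nonpathogen`); exactly one focal.
#' @param n_per_category Named integer vector with entries `specific`,
#'   `with_pathogen`, `shared_both_groups`, `with_nonpathogen`: how many
#'   focal genes to plant with each presence pattern.
#' @param n_families,family_size Single-linkage families planted as chains of
#'   focal-only genes (ground-truth category: specific).
#' @param n_decoys Number of decoy hits (cycled over the three violation
#'   types).
#' @param gene_length Protein length used for all genes.
#' @param seed Integer seed.
#' @return List: `hits` (14-column hit data.frame with genome labels),
#'   `genome_map` (data.frame gene_id, genome), `focal_genes`, and `truth`
#'   (list with `categories`, `families`, `universal_groups`).
#' @export
simulate_hit_table <- function(genome_groups,
                               n_per_category = c(specific = 10,
                                                  with_pathogen = 10,
                                                  shared_both_groups = 10,
                                                  with_nonpathogen = 10),
                               n_families = 4, family_size = 5,
                               n_decoys = 9, gene_length = 300L, seed) {
  focal <- names(genome_groups)[genome_groups == "focal"]
  stopifnot(length(focal) == 1L)
  pathogens <- names(genome_groups)[genome_groups == "pathogen"]
  nonpath <- names(genome_groups)[genome_groups == "nonpathogen"]
  stopifnot(length(pathogens) >= 1L, length(nonpath) >= 1L)

  rows <- list()
  genome_map <- list()
  add_gene <- function(genome, id) {
    genome_map[[length(genome_map) + 1L]] <<- data.frame(
      gene_id = id, genome = genome, stringsAsFactors = FALSE)
  }
  emit <- function(q, s, pident, len, evalue, bitscore) {
    rows[[length(rows) + 1L]] <<- data.frame(
      qseqid = q, sseqid = s, pident = pident, length = len,
      mismatch = round(len * (100 - pident) / 100), gapopen = 0L,
      qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = evalue, bitscore = bitscore,
      qlen = gene_length, slen = gene_length, stringsAsFactors = FALSE)
  }
  emit_pair <- function(a, b, pident, bitscore) {
    emit(a, b, pident, gene_length, 1e-80, bitscore)
    emit(b, a, pident, gene_length, 1e-80, bitscore)
  }

  withr::with_seed(seed, {
    truth_cat <- list()
    universal <- list()
    gi <- 0L
    for (cat in names(n_per_category)) {
      present <- switch(cat,
        specific = character(),
        with_pathogen = pathogens,
        shared_both_groups = c(pathogens, nonpath),
        with_nonpathogen = nonpath,
        stop("unknown category: ", cat))
      for (k in seq_len(n_per_category[[cat]])) {
        gi <- gi + 1L
        fg <- sprintf("%s_g%03d", focal, gi)
        add_gene(focal, fg)
        truth_cat[[length(truth_cat) + 1L]] <- data.frame(
          gene_id = fg, category = cat, stringsAsFactors = FALSE)
        members <- stats::setNames(fg, focal)
        for (g in present) {
          pid <- sprintf("%s_g%03d", g, gi)
          add_gene(g, pid)
          members[g] <- pid
        }
        # full clique among all members so groups/categories are exact
        if (length(members) > 1L) {
          cmb <- utils::combn(unname(members), 2)
          bs <- 400 + stats::runif(1, 0, 50)
          for (cidx in seq_len(ncol(cmb))) {
            emit_pair(cmb[1, cidx], cmb[2, cidx],
                      pident = 80 + stats::runif(1, 0, 15), bitscore = bs)
          }
        }
        if (cat == "shared_both_groups" &&
            setequal(names(members), names(genome_groups))) {
          universal[[length(universal) + 1L]] <- members
        }
      }
    }
    # single-linkage family chains within the focal proteome
    truth_fam <- list()
    for (f in seq_len(n_families)) {
      ids <- sprintf("%s_fam%02d_m%02d", focal, f, seq_len(family_size))
      for (id in ids) {
        add_gene(focal, id)
        truth_cat[[length(truth_cat) + 1L]] <- data.frame(
          gene_id = id, category = "specific", stringsAsFactors = FALSE)
      }
      if (family_size >= 2L) {
        for (k in seq_len(family_size - 1L)) {
          emit_pair(ids[k], ids[k + 1L],
                    pident = 70 + stats::runif(1, 0, 20),
                    bitscore = 300 + stats::runif(1, 0, 50))
        }
      }
      truth_fam[[f]] <- ids
    }
    # decoys, each violating exactly one filter
    gm <- do.call(rbind, genome_map)
    focal_ids <- gm$gene_id[gm$genome == focal]
    other_ids <- gm$gene_id[gm$genome != focal]
    if (n_decoys > 0L && length(other_ids)) {
      kinds <- rep(c("evalue", "identity", "coverage"),
                   length.out = n_decoys)
      for (k in seq_len(n_decoys)) {
        q <- sample(focal_ids, 1)
        s <- sample(other_ids, 1)
        switch(kinds[k],
          evalue = emit(q, s, 85, gene_length, 1e-3, 50),
          identity = emit(q, s, 20, gene_length, 1e-80, 400),
          coverage = emit(q, s, 85, round(0.4 * gene_length), 1e-80, 150))
      }
    }
  })
  genome_map <- do.call(rbind, genome_map)
  hits <- do.call(rbind, rows)
  if (!is.null(hits)) hits <- annotate_genomes(hits, genome_map)
  categories <- do.call(rbind, truth_cat)
  rownames(categories) <- NULL
  list(hits = hits, genome_map = genome_map,
       focal_genes = genome_map$gene_id[genome_map$genome == focal],
       truth = list(categories = categories, families = truth_fam,
                    universal_groups = universal))
}

#' Simulate a replicated qPCR Ct table with a known fold change
#'
#' Constructed by inverting the 2^-ddCt formula: the reference gene sits at a
#' fixed Ct in both conditions, the target sits `log2(true_fold)` cycles
#' lower in the treatment than in the control condition, and Gaussian noise
#' of sd `noise_sd` is added to every well. With `noise_sd = 0`,
#' [ddct_fold_change()] returns `true_fold` exactly.
#'
#' @param true_fold Planted fold change (> 0).
#' @param replicates Replicates per (gene, condition) cell.
#' @param noise_sd Gaussian noise sd in cycles.
#' @param seed Integer seed.
#' @param target,reference Gene ids used in the table.
#' @param base_ct_target,base_ct_reference Control-condition mean Ct values.
#' @return Ct table data.frame (gene_id, condition, replicate, ct).
#' @export
simulate_ct <- function(true_fold, replicates = 3L, noise_sd = 0, seed,
                        target = "target", reference = "18S",
                        base_ct_target = 24, base_ct_reference = 15) {
  stopifnot(true_fold > 0, replicates >= 1L, noise_sd >= 0)
  cells <- expand.grid(gene_id = c(target, reference),
                       condition = c("treatment", "control"),
                       replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
  mean_ct <- ifelse(cells$gene_id == reference, base_ct_reference,
                    ifelse(cells$condition == "treatment",
                           base_ct_target - log2(true_fold), base_ct_target))
  withr::with_seed(seed, {
    cells$ct <- mean_ct + stats::rnorm(nrow(cells), 0, noise_sd)
  })
  cells
}

#' Simulate a replicated spot-intensity table with planted fold changes
#'
#' Intensities are log-normal: log2 intensity = baseline (+ log2 planted fold
#' in the treatment) + Gaussian noise. Spots without a planted fold are null
#' (fold 1).
#'
#' @param n_spots Total number of spots (ids `spot001`...).
#' @param planted_folds Named numeric vector, names in `spot001`-style ids
#'   (or plain indices coerced to them), giving each planted spot's true
#'   treatment/control fold.
#' @param noise_sd Gaussian sd on the log2 scale.
#' @param replicates Replicates per condition.
#' @param seed Integer seed.
#' @param base_log2 Baseline log2 intensity.
#' @return List: `spots` (data.frame spot_id, condition, replicate,
#'   intensity) and `truth` (data.frame spot_id, true_fold).
#' @export
simulate_spots <- function(n_spots = 100L, planted_folds = numeric(),
                           noise_sd = 0.2, replicates = 3L, seed,
                           base_log2 = 10) {
  stopifnot(n_spots >= 1L, replicates >= 2L, noise_sd >= 0)
  ids <- sprintf("spot%03d", seq_len(n_spots))
  if (length(planted_folds) && is.null(names(planted_folds))) {
    names(planted_folds) <- ids[seq_along(planted_folds)]
  }
  true_fold <- stats::setNames(rep(1, n_spots), ids)
  true_fold[names(planted_folds)] <- planted_folds
  grid <- expand.grid(spot_id = ids,
                      condition = c("treatment", "control"),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  mu <- base_log2 +
    ifelse(grid$condition == "treatment", log2(true_fold[grid$spot_id]), 0)
  withr::with_seed(seed, {
    grid$intensity <- 2^(mu + stats::rnorm(nrow(grid), 0, noise_sd))
  })
  list(spots = grid,
       truth = data.frame(spot_id = ids, true_fold = unname(true_fold),
                          stringsAsFactors = FALSE))
}
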