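# RIP (repeat-induced point mutation) relic detection.
#
# RIP mutates C->T in duplicated sequence, preferentially at CpA dinucleotides
# (TpG on the reverse strand). It leaves a compositional fingerprint that two
# dinucleotide ratios capture:
#   product index    TpA/ApT               -- elevated by RIP (TpA is the product)
#   substrate index  (CpA+TpG)/(ApC+GpT)   -- depleted by RIP (CpA/TpG are substrates)
# A window is RIP-positive when product >= 0.89 AND substrate <= 1.03
# (inclusive bounds). Zero-denominator ratios are carried as NA and can never
# satisfy a threshold: a 0/0 window is evidence of nothing.

DINUCLEOTIDES <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0))

#' Count overlapping dinucleotides
#'
#' Counts all overlapping residue pairs left to right. Pairs containing `N`
#' are excluded from the counts (positions still advance by one), so ratios
#' are not biased near assembly gaps.
#'
#' @param seq Sequence over `{A,C,G,T,N}` (any case).
#' @return List with `counts` (named integer vector over the 16 dinucleotides),
#'   `valid_pairs` (their sum) and `base_counts` (named counts of A,C,G,T,N).
#' @export
count_dinucleotides <- function(seq) {
  s <- normalize_seq(seq)
  n <- nchar(s)
  chars <- if (n) strsplit(s, "", fixed = TRUE)[[1]] else character()
  base_counts <- table(factor(chars, levels = SEQ_ALPHABET))
  counts <- stats::setNames(integer(16), DINUCLEOTIDES)
  if (n >= 2L) {
    left <- chars[-n]
    right <- chars[-1L]
    ok <- left != "N" & right != "N"
    pairs <- paste0(left[ok], right[ok])
    tab <- table(factor(pairs, levels = DINUCLEOTIDES))
    counts[] <- as.integer(tab)
  }
  list(counts = counts, valid_pairs = sum(counts),
       base_counts = stats::setNames(as.integer(base_counts), SEQ_ALPHABET))
}

.safe_ratio <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Compute the two RIP indices and AT content from dinucleotide counts
#'
#' @param counts Result of [count_dinucleotides()].
#' @return List with `product_index` (TpA/ApT), `substrate_index`
#'   ((CpA+TpG)/(ApC+GpT)) and `at_content` ((A+T)/(A+C+G+T), N excluded).
#'   Ratios with a zero denominator are `NA` (undefined, never 0).
#' @export
rip_indices <- function(counts) {
  dn <- counts$counts
  bc <- counts$base_counts
  acgt <- sum(bc[c("A", "C", "G", "T")])
  list(
    product_index = .safe_ratio(dn[["TA"]], dn[["AT"]]),
    substrate_index = .safe_ratio(dn[["CA"]] + dn[["TG"]],
                                  dn[["AC"]] + dn[["GT"]]),
    at_content = if (acgt == 0) NA_real_ else (bc[["A"]] + bc[["T"]]) / acgt
  )
}

#' Default RIP-calling parameters
#'
#' 200-bp windows shifted by 100 bp, flagged when TpA/ApT >= 0.89 and
#' (CpA+TpG)/(ApC+GpT) <= 1.03.
#'
#' @param window,shift Window size and shift in bp.
#' @param product_min,substrate_max Inclusive thresholds on the two indices.
#' @return Named list of validated parameters.
#' @export
rip_params <- function(window = 200L, shift = 100L,
                       product_min = 0.89, substrate_max = 1.03) {
  stopifnot(window >= 2L, shift >= 1L, shift <= window,
            product_min > 0, substrate_max > 0)
  list(window = as.integer(window), shift = as.integer(shift),
       product_min = product_min, substrate_max = substrate_max)
}

#' Slide RIP-index windows along a contig
#'
#' Windows start at 0, shift, 2*shift, ...; only full-length windows are
#' scored (trailing partial windows are dropped — index variance explodes on
#' short windows). A contig shorter than one window yields zero rows.
#'
#' The scan is vectorized with cumulative sums over per-position indicator
#' vectors, so whole-genome scans at 200/100 are cheap.
#'
#' @param seq Contig sequence.
#' @param params Parameters from [rip_params()].
#' @param contig_id Contig id used in the output.
#' @return data.frame with columns contig, start, end, at_content,
#'   product_index, substrate_index, rip_positive.
#' @export
scan_windows <- function(seq, params = rip_params(), contig_id = "contig") {
  s <- normalize_seq(seq)
  n <- nchar(s)
  w <- params$window
  empty <- data.frame(contig = character(), start = numeric(), end = numeric(),
                      at_content = numeric(), product_index = numeric(),
                      substrate_index = numeric(), rip_positive = logical())
  if (n < w) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  left <- chars[-n]
  right <- chars[-1L]
  pair_cum <- function(a, b) cumsum(c(0L, left == a & right == b))
  cTA <- pair_cum("T", "A"); cAT <- pair_cum("A", "T")
  cCA <- pair_cum("C", "A"); cTG <- pair_cum("T", "G")
  cAC <- pair_cum("A", "C"); cGT <- pair_cum("G", "T")
  cA <- cumsum(c(0L, chars == "A")); cT <- cumsum(c(0L, chars == "T"))
  cN <- cumsum(c(0L, chars == "N"))
  starts <- seq.int(0L, n - w, by = params$shift)
  # pairs inside window [s, s+w): left positions s+1 .. s+w-1 (1-based)
  lo <- starts + 1L  # cumsum index of position `starts` (prefix length)
  hi <- starts + w
  win_pair <- function(cv) cv[hi] - cv[lo]
  ta <- win_pair(cTA); at <- win_pair(cAT)
  ca <- win_pair(cCA); tg <- win_pair(cTG)
  ac <- win_pair(cAC); gt <- win_pair(cGT)
  nA <- cA[hi + 1L] - cA[lo]; nT <- cT[hi + 1L] - cT[lo]
  nN <- cN[hi + 1L] - cN[lo]
  acgt <- w - nN
  product <- ifelse(at == 0, NA_real_, ta / at)
  substrate <- ifelse(ac + gt == 0, NA_real_, (ca + tg) / (ac + gt))
  at_content <- ifelse(acgt == 0, NA_real_, (nA + nT) / acgt)
  positive <- !is.na(product) & !is.na(substrate) &
    product >= params$product_min & substrate <= params$substrate_max
  data.frame(contig = contig_id, start = starts, end = starts + w,
             at_content = at_content, product_index = product,
             substrate_index = substrate, rip_positive = positive)
}

#' Scan every contig of a genome
#'
#' @param contigs Named character vector of contig sequences.
#' @param params Parameters from [rip_params()].
#' @return Row-bound window table over all contigs.
#' @export
scan_genome <- function(contigs, params = rip_params()) {
  out <- mapply(scan_windows, contigs, contig_id = names(contigs),
                MoreArgs = list(params = params), SIMPLIFY = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of the genome covered by RIP-positive windows
#'
#' The headline "about one third RIP-positive" quantity: the union of
#' RIP-positive windows, as a fraction of total sequence length. Covered
#' bases are aggregated over all contigs before dividing, so contigs are
#' length-weighted as in a genome-wide fraction. `mode = "windows"` instead
#' returns the fraction of windows flagged.
#'
#' @param windows Window table from [scan_windows()]/[scan_genome()].
#' @param contig_lengths Named numeric vector (or a single length).
#' @param mode `"bases"` (default) or `"windows"`.
#' @return Fraction in `[0, 1]`.
#' @export
rip_region_fraction <- function(windows, contig_lengths,
                                mode = c("bases", "windows")) {
  mode <- match.arg(mode)
  if (mode == "windows") {
    if (nrow(windows) == 0L) return(0)
    return(mean(windows$rip_positive))
  }
  total <- sum(contig_lengths)
  if (total == 0) stop("total contig length is zero")
  pos <- windows[windows$rip_positive, , drop = FALSE]
  if (nrow(pos) == 0L) return(0)
  merged <- merge_intervals(pos[, c("contig", "start", "end")])
  sum(merged$end - merged$start) / total
}

#' Summarize AT content and RIP indices per feature class
#'
#' For every feature class of a partition, reports (a) whole-class indices
#' from dinucleotide counts pooled across the class's extracted sequences —
#' counts are summed per sequence, so no artificial junction dinucleotides
#' are introduced — and (b) window-level statistics (window count, mean of
#' each defined index, mean AT content, RIP-positive window fraction) at each
#' requested window/shift setting.
#'
#' @param contigs Named character vector of contig sequences.
#' @param partition Feature partition from [partition_from_gff()] (or any
#'   named list of interval data.frames with a `contig_lengths` attribute).
#' @param settings List of `c(window, shift)` pairs; defaults to the 500/100
#'   and 200/100 settings.
#' @param product_min,substrate_max Window-call thresholds.
#' @return data.frame with one pooled row (`scope == "pooled"`) and one row
#'   per window setting (`scope == "windows"`) for each class.
#' @export
summarize_by_class <- function(contigs, partition,
                               settings = list(c(500L, 100L), c(200L, 100L)),
                               product_min = 0.89, substrate_max = 1.03) {
  rows <- list()
  for (cls in names(partition)) {
    iv <- partition[[cls]]
    seqs <- extract_intervals(contigs, iv)
    pooled <- stats::setNames(integer(16), DINUCLEOTIDES)
    bases <- stats::setNames(integer(5), SEQ_ALPHABET)
    for (sq in seqs) {
      cd <- count_dinucleotides(sq)
      pooled <- pooled + cd$counts
      bases <- bases + cd$base_counts
    }
    idx <- rip_indices(list(counts = pooled, base_counts = bases))
    rows[[length(rows) + 1L]] <- data.frame(
      class = cls, scope = "pooled", window = NA_integer_, shift = NA_integer_,
      total_length = sum(iv$end - iv$start), n_windows = NA_integer_,
      at_content = idx$at_content, product_index = idx$product_index,
      substrate_index = idx$substrate_index, frac_rip_positive = NA_real_)
    for (st in settings) {
      pars <- rip_params(st[[1]], st[[2]], product_min, substrate_max)
      wins <- lapply(seq_along(seqs), function(i) {
        scan_windows(seqs[[i]], pars,
                     contig_id = paste0(iv$contig[i], ":", iv$start[i]))
      })
      wins <- if (length(wins)) do.call(rbind, wins) else NULL
      nw <- if (is.null(wins)) 0L else nrow(wins)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, scope = "windows",
        window = pars$window, shift = pars$shift,
        total_length = sum(iv$end - iv$start), n_windows = nw,
        at_content = if (nw) mean(wins$at_content, na.rm = TRUE) else NA_real_,
        product_index = if (nw) mean(wins$product_index, na.rm = TRUE) else NA_real_,
        substrate_index = if (nw) mean(wins$substrate_index, na.rm = TRUE) else NA_real_,
        frac_rip_positive = if (nw) mean(wins$rip_positive) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write scanned windows as BED6 and as a full TSV
#'
#' The BED score is the product index scaled by 1000 and rounded (capped at
#' 1000 as BED requires); undefined indices get score 0.
#'
#' @param windows Window table.
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_windows <- function(windows, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    score <- ifelse(is.na(windows$product_index), 0,
                    pmin(1000, round(windows$product_index * 1000)))
    bed_df <- data.frame(windows$contig, windows$start, windows$end,
                         paste0("win", seq_len(nrow(windows))), score, ".")
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv)) {
    utils::write.table(windows, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed = bed, tsv = tsv))
}
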