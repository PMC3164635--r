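# qPCR 2^-ddCt relative quantification against an internal reference gene
# (18S rDNA in the original assays) and differential protein-spot calling
# at a fold-change threshold with an unpaired significance test.

.check_ct_table <- function(ct) {
  need <- c("gene_id", "condition", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  ct
}

.cell_mean <- function(ct, gene, condition) {
  v <- ct$ct[ct$gene_id == gene & ct$condition == condition]
  if (length(v) == 0L) {
    stop("no Ct values for gene '", gene, "' in condition '", condition, "'")
  }
  mean(v)
}

#' Relative fold change by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (gene, condition) cell first, then
#' dCt = mean Ct(target) - mean Ct(reference gene) within each condition,
#' ddCt = dCt(treatment) - dCt(control), and fold = 2^-ddCt. With
#' `per_replicate = TRUE` the ddCt is instead computed per replicate pairing
#' (replicate i of each cell) and averaged before exponentiation.
#'
#' @param ct Ct table: data.frame with columns gene_id, condition, replicate,
#'   ct.
#' @param target Target gene id.
#' @param reference Internal-control gene id (e.g. `"18S"`).
#' @param treatment,control Condition labels.
#' @param per_replicate Average ddCt over replicate pairings instead of
#'   working on cell means.
#' @return data.frame gene_id, delta_delta_ct, fold_change (one row).
#' @export
ddct_fold_change <- function(ct, target, reference,
                             treatment = "treatment", control = "control",
                             per_replicate = FALSE) {
  ct <- .check_ct_table(ct)
  if (per_replicate) {
    cell <- function(gene, cond) {
      d <- ct[ct$gene_id == gene & ct$condition == cond, , drop = FALSE]
      if (nrow(d) == 0L) stop("no Ct values for gene '", gene,
                              "' in condition '", cond, "'")
      d$ct[order(d$replicate)]
    }
    ddct_i <- (cell(target, treatment) - cell(reference, treatment)) -
      (cell(target, control) - cell(reference, control))
    ddct <- mean(ddct_i)
  } else {
    dct_t <- .cell_mean(ct, target, treatment) -
      .cell_mean(ct, reference, treatment)
    dct_c <- .cell_mean(ct, target, control) -
      .cell_mean(ct, reference, control)
    ddct <- dct_t - dct_c
  }
  data.frame(gene_id = target, delta_delta_ct = ddct,
             fold_change = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Fold changes for several target genes
#'
#' @inheritParams ddct_fold_change
#' @param targets Character vector of target gene ids.
#' @return data.frame, one row per target.
#' @export
ddct_table <- function(ct, targets, reference,
                       treatment = "treatment", control = "control") {
  out <- lapply(targets, function(g) {
    ddct_fold_change(ct, g, reference, treatment, control)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call differentially expressed protein spots
#'
#' fold = mean(treatment)/mean(control) per spot; a spot is `up` when
#' fold >= `fold_threshold` and p < `alpha`, `down` when
#' fold <= 1/`fold_threshold` and p < `alpha`, else `unchanged`. P-values
#' come from a two-sided two-sample unequal-variance (Welch) t-test on
#' log-transformed intensities, optionally multiplicity-adjusted.
#'
#' @param spots data.frame with columns spot_id, condition, replicate,
#'   intensity (> 0; intensities are log-transformed for the test).
#' @param fold_threshold Fold-change threshold (default 1.5).
#' @param alpha Significance level on the (adjusted) p-value (default 0.05).
#' @param treatment,control Condition labels.
#' @param p_adjust Method for [stats::p.adjust()]; default `"none"` (raw
#'   p-values, as in the original spot analysis).
#' @return data.frame spot_id, fold_change, p_value, label.
#' @export
differential_spots <- function(spots, fold_threshold = 1.5, alpha = 0.05,
                               treatment = "treatment", control = "control",
                               p_adjust = "none") {
  need <- c("spot_id", "condition", "replicate", "intensity")
  if (!all(need %in% names(spots))) {
    stop("spot table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(spots$intensity < 0)) stop("negative intensity")
  if (any(spots$intensity == 0)) {
    stop("zero intensity cannot be log-transformed for testing")
  }
  ids <- sort(unique(spots$spot_id))
  res <- lapply(ids, function(id) {
    trt <- spots$intensity[spots$spot_id == id & spots$condition == treatment]
    ctl <- spots$intensity[spots$spot_id == id & spots$condition == control]
    if (length(trt) < 2L || length(ctl) < 2L) {
      stop("spot '", id, "': need >= 2 replicates per condition")
    }
    m_ctl <- mean(ctl)
    if (m_ctl == 0) stop("spot '", id, "': zero control mean")
    fold <- mean(trt) / m_ctl
    p <- if (stats::sd(log(trt)) == 0 && stats::sd(log(ctl)) == 0) {
      # degenerate: no within-group variance; identical means -> no evidence
      if (isTRUE(all.equal(mean(log(trt)), mean(log(ctl))))) 1 else 0
    } else {
      stats::t.test(log(trt), log(ctl), var.equal = FALSE)$p.value
    }
    data.frame(spot_id = id, fold_change = fold, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$label <- ifelse(
    out$fold_change >= fold_threshold & out$p_adjusted < alpha, "up",
    ifelse(out$fold_change <= 1 / fold_threshold & out$p_adjusted < alpha,
           "down", "unchanged"))
  rownames(out) <- NULL
  out
}
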