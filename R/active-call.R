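# FPR-controlled active-construct calling.
#
# An essential-targeting construct is "active" when it is more depleted than
# a depletion threshold set on the non-essential-targeting constructs at a
# chosen false positive rate (the screens use FPR = 5%). This is a library
# quality-control metric, not a hit caller.

#' Depletion threshold at a given false positive rate
#'
#' Returns the lower-tail empirical quantile of the non-essential fold-change
#' distribution such that at most floor(fpr * n) values lie strictly below
#' it (exactly that many when values are distinct). Ties sit at or above the
#' threshold, keeping the realized FPR conservative.
#'
#' @param lfc_nonessential log2 fold changes of non-essential-targeting
#'   constructs.
#' @param fpr false positive rate in (0, 1).
#' @return threshold (log2 units).
#' @export
fpr_threshold <- function(lfc_nonessential, fpr) {
  n <- length(lfc_nonessential)
  stopifnot(n > 0L, fpr > 0, fpr < 1)
  k <- floor(fpr * n)
  if (k < 1) stopf("fpr * n < 1: threshold undefined (n = %d, fpr = %g)", n, fpr)
  sort(lfc_nonessential)[k + 1L]
}

#' Active-construct fraction at a controlled FPR
#'
#' Thresholds are computed per replicate and per timepoint on the
#' non-essential constructs of that sample; the active fraction is the
#' proportion of essential-targeting constructs strictly below the
#' threshold. The summary reports mean and s.d. across replicates per
#' timepoint.
#'
#' @param fc a `FoldChangeMatrix`.
#' @param library the `GuideLibrary` mapping constructs to genes.
#' @param refs a `ReferenceSets`.
#' @param fpr false positive rate (default 0.05).
#' @return an `ActiveCallResult`: list with `fpr`, `by_sample`
#'   (timepoint/replicate/threshold_lfc/active_fraction) and `summary`
#'   (per-timepoint mean and s.d.).
#' @export
active_fraction <- function(fc, library, refs, fpr = 0.05) {
  stopifnot(inherits(fc, "FoldChangeMatrix"), inherits(refs, "ReferenceSets"))
  genes <- construct_genes(library)[rownames(fc$lfc)]
  is_ess <- genes %in% refs$essential
  is_non <- genes %in% refs$non_essential
  if (!any(is_ess)) stopf("no essential-targeting constructs in fold-change matrix")
  if (!any(is_non)) stopf("no non-essential-targeting constructs in fold-change matrix")

  by_sample <- fc$samples
  by_sample$threshold_lfc <- NA_real_
  by_sample$active_fraction <- NA_real_
  for (j in seq_len(ncol(fc$lfc))) {
    thr <- fpr_threshold(fc$lfc[is_non, j], fpr)
    by_sample$threshold_lfc[j] <- thr
    by_sample$active_fraction[j] <- mean(fc$lfc[is_ess, j] < thr)
  }
  tps <- sort(unique(by_sample$timepoint))
  summary <- data.frame(
    timepoint = tps,
    mean_active_fraction = vapply(tps, function(t) {
      mean(by_sample$active_fraction[by_sample$timepoint == t])
    }, numeric(1)),
    sd_active_fraction = vapply(tps, function(t) {
      stats::sd(by_sample$active_fraction[by_sample$timepoint == t])
    }, numeric(1))
  )
  structure(list(fpr = fpr, by_sample = by_sample, summary = summary),
            class = "ActiveCallResult")
}

#' @export
print.ActiveCallResult <- function(x, ...) {
  cat(sprintf("Active constructs at FPR %.0f%%:\n", 100 * x$fpr))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  T%d: %.1f%% +/- %.1f%%\n", x$summary$timepoint[i],
                100 * x$summary$mean_active_fraction[i],
                100 * x$summary$sd_active_fraction[i]))
  }
  invisible(x)
}
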