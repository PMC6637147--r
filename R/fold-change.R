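# Count normalization and log2 fold change against each replicate's
# reference sample.

#' Normalize count columns to a common depth
#'
#' Each sample column is scaled to `scale` total reads, then a pseudocount
#' is added so downstream log-ratios are finite.
#'
#' @param cm a `CountMatrix`.
#' @param scale target total reads per sample (default 1e7).
#' @param pseudocount added after scaling (default 0.5).
#' @return numeric matrix, same shape as the counts.
#' @export
normalize_counts <- function(cm, scale = 1e7, pseudocount = 0.5) {
  stopifnot(inherits(cm, "CountMatrix"), scale > 0, pseudocount > 0)
  tot <- colSums(cm$counts)
  if (any(tot == 0)) {
    stopf("cannot normalize all-zero sample column '%s'",
          colnames(cm$counts)[tot == 0][1L])
  }
  sweep(cm$counts, 2L, scale / tot, `*`) + pseudocount
}

#' Log2 fold change against the replicate reference
#'
#' For every non-reference sample, lfc = log2(normalized sample) -
#' log2(normalized reference of the same replicate). Fold changes are
#' computed within replicate; averaging across replicates happens only at
#' reporting time.
#'
#' @inheritParams normalize_counts
#' @return a `FoldChangeMatrix`: list with `lfc` (constructs x non-reference
#'   samples, log2 units) and `samples` (their parsed labels).
#' @export
log2_fold_change <- function(cm, scale = 1e7, pseudocount = 0.5) {
  norm <- normalize_counts(cm, scale, pseudocount)
  s <- cm$samples
  nonref <- which(!s$is_reference)
  lfc <- matrix(NA_real_, nrow = nrow(norm), ncol = length(nonref),
                dimnames = list(rownames(norm), s$label[nonref]))
  for (i in seq_along(nonref)) {
    j <- nonref[i]
    ref <- which(s$is_reference & s$replicate == s$replicate[j])
    if (length(ref) != 1L) {
      stopf("no reference sample for replicate %d", s$replicate[j])
    }
    lfc[, i] <- log2(norm[, j]) - log2(norm[, ref])
  }
  structure(list(lfc = lfc, samples = s[nonref, , drop = FALSE]),
            class = "FoldChangeMatrix")
}

#' @export
print.FoldChangeMatrix <- function(x, ...) {
  cat(sprintf("FoldChangeMatrix: %d constructs x %d samples\n",
              nrow(x$lfc), ncol(x$lfc)))
  invisible(x)
}

#' Replicate-averaged log2 fold change at one timepoint
#'
#' @param fc a `FoldChangeMatrix`.
#' @param timepoint which timepoint to average; defaults to the endpoint
#'   (largest timepoint).
#' @return named numeric vector, one value per construct.
#' @export
replicate_mean_lfc <- function(fc, timepoint = NULL) {
  stopifnot(inherits(fc, "FoldChangeMatrix"))
  if (is.null(timepoint)) timepoint <- max(fc$samples$timepoint)
  j <- which(fc$samples$timepoint == timepoint)
  if (!length(j)) stopf("no samples at timepoint %s", timepoint)
  rowMeans(fc$lfc[, j, drop = FALSE])
}
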