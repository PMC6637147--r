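# Position-specific nucleotide preference scoring of AsCpf1 protospacers.
#
# Within each essential gene of a mono-cistronic screen, the most depleted
# guide is the high performer and the least depleted the low performer; the
# per-position nucleotide frequency of the low set subtracted from the high
# set, averaged over bootstrap resamples of the gene pairs, yields a
# 4 x 20 preference matrix. A guide's score is the sum of its positional
# cells; score > 0 predicts a high-performing guide. Position 1 is the
# protospacer base adjacent to the PAM.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Split guides per gene into high / low / median performers
#'
#' Uses replicate-averaged log2 fold change at the chosen timepoint. Per
#' essential gene with at least 3 scored guides: high performer = most
#' depleted guide (minimum lfc), low performer = least depleted; ties go to
#' the lower guide (cistron/input) index. The remaining median guides form
#' the validation holdout. Non-essential genes are never used.
#'
#' @param fc a `FoldChangeMatrix` from a mono-cistronic screen.
#' @param library the mono-cistronic `GuideLibrary`.
#' @param essential_genes character vector of essential gene names.
#' @param timepoint timepoint for the lfc (default: endpoint).
#' @return list with `pairs` (gene, high/low guide ids, sequences, lfcs),
#'   `holdout` (gene, guide_id, sequence, lfc) and `excluded` genes.
#' @export
classify_extremes <- function(fc, library, essential_genes, timepoint = NULL) {
  stopifnot(inherits(fc, "FoldChangeMatrix"))
  if (!library$mode %in% c("cas9_mono", "cpf1_mono")) {
    stopf("classify_extremes requires a mono-cistronic library")
  }
  lfc <- replicate_mean_lfc(fc, timepoint)
  g <- library$guides[library$guides$construct_id %in% names(lfc) &
                        library$guides$gene %in% essential_genes, ]
  g$lfc <- as.numeric(lfc[g$construct_id])

  by_gene <- split(seq_len(nrow(g)), g$gene)
  n_per <- lengths(by_gene)
  excluded <- names(by_gene)[n_per < 3L]
  if (length(excluded)) {
    warnf("%d genes with fewer than 3 scored guides excluded", length(excluded))
  }
  by_gene <- by_gene[n_per >= 3L]

  pairs <- do.call(rbind, lapply(names(by_gene), function(gene) {
    ix <- by_gene[[gene]]
    i_hi <- ix[which.min(g$lfc[ix])]          # ties: lowest input index
    rest <- setdiff(ix, i_hi)
    i_lo <- rest[which.max(g$lfc[rest])]
    data.frame(gene = gene,
               high_guide = g$construct_id[i_hi], high_sequence = g$sequence[i_hi],
               high_lfc = g$lfc[i_hi],
               low_guide = g$construct_id[i_lo], low_sequence = g$sequence[i_lo],
               low_lfc = g$lfc[i_lo], stringsAsFactors = FALSE)
  }))
  med_ix <- unlist(lapply(names(by_gene), function(gene) {
    ix <- by_gene[[gene]]
    i_hi <- ix[which.min(g$lfc[ix])]
    rest <- setdiff(ix, i_hi)
    i_lo <- rest[which.max(g$lfc[rest])]
    setdiff(ix, c(i_hi, i_lo))
  }))
  holdout <- data.frame(gene = g$gene[med_ix], guide_id = g$construct_id[med_ix],
                        sequence = g$sequence[med_ix], lfc = g$lfc[med_ix],
                        stringsAsFactors = FALSE)
  list(pairs = pairs, holdout = holdout, excluded = excluded)
}

#' @noRd
nt_freq <- function(seqs) {
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  vapply(seq_len(20L), function(p) {
    tabulate(match(chars[, p], NUCLEOTIDES), 4L) / length(seqs)
  }, numeric(4L))
}

#' Fit the bootstrapped nucleotide preference matrix
#'
#' Per bootstrap, gene pairs (a high and a low guide travelling together)
#' are resampled with replacement to the original size; the cell value is
#' the per-position nucleotide frequency among high guides minus that among
#' low guides. The returned table is the mean over bootstraps; each
#' bootstrap's columns sum to zero exactly, so the aggregate columns do too.
#'
#' @param high,low character vectors of paired 20-mer protospacers (index i
#'   of both belongs to the same gene).
#' @param n_bootstraps number of bootstrap resamples (default 100).
#' @param seed RNG seed.
#' @return a `ScoreTable`: 4 x 20 matrix (rows A, C, G, T; columns
#'   protospacer positions 1..20, PAM-adjacent first) with attributes
#'   `n_bootstraps` and `sd` (per-cell bootstrap s.d.).
#' @export
fit_score_table <- function(high, low, n_bootstraps = 100, seed = 1) {
  n <- length(high)
  if (n == 0L) stopf("empty pair list")
  stopifnot(length(low) == n, n_bootstraps >= 1)
  if (n < 30L) warnf("only %d pairs; the preference matrix will be noisy", n)
  check_guide_seqs(high, "high guide")
  check_guide_seqs(low, "low guide")
  tabs <- with_seed(seed, {
    lapply(seq_len(n_bootstraps), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      nt_freq(high[ix]) - nt_freq(low[ix])
    })
  })
  arr <- array(unlist(tabs), dim = c(4L, 20L, n_bootstraps))
  tab <- apply(arr, c(1L, 2L), mean)
  sd_tab <- apply(arr, c(1L, 2L), stats::sd)
  dimnames(tab) <- dimnames(sd_tab) <- list(NUCLEOTIDES, as.character(1:20))
  structure(tab, n_bootstraps = n_bootstraps, sd = sd_tab,
            class = c("ScoreTable", "matrix", "array"))
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat(sprintf("ScoreTable: 4 nt x 20 positions (mean of %d bootstraps)\n",
              attr(x, "n_bootstraps")))
  print(round(unclass(x)[, 1:8], 3))
  cat("  ... (positions 9-20 omitted)\n")
  invisible(x)
}

#' Score a guide against a preference matrix
#'
#' The guide score is the sum over the 20 positions of the matrix cell for
#' the guide's base at that position; score > 0 predicts a high-performing
#' guide, score <= 0 a low-performing one.
#'
#' @param guides character vector of 20-mer protospacers (ACGT).
#' @param table a `ScoreTable`.
#' @return data.frame with `guide`, `score`, `predicted_class`.
#' @export
score_guides <- function(guides, table) {
  stopifnot(inherits(table, "ScoreTable"))
  check_guide_seqs(guides)
  chars <- matrix(unlist(strsplit(guides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(guides), byrow = TRUE)
  score <- vapply(seq_along(guides), function(i) {
    sum(unclass(table)[cbind(chars[i, ], 1:20)])
  }, numeric(1))
  data.frame(guide = guides, score = score,
             predicted_class = ifelse(score > 0, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Score a single guide
#' @inheritParams score_guides
#' @param guide a single 20-mer.
#' @return list with `guide`, `score`, `predicted_class`.
#' @export
score_guide <- function(guide, table) {
  as.list(score_guides(guide, table)[1L, ])
}

#' Validate a preference matrix on held-out median guides
#'
#' Reports the Spearman correlation between guide score and fold change
#' (negative when the matrix is informative: higher score, deeper
#' depletion), the mean fold change of predicted-high vs predicted-low
#' guides and a two-sided two-sample t statistic for their difference.
#'
#' @param holdout data.frame with `sequence` and `lfc` columns (at least 10
#'   guides), disjoint from the training pairs.
#' @param table a `ScoreTable`.
#' @return list with `n`, `spearman_rho`, `spearman_p`, `mean_lfc_high`,
#'   `mean_lfc_low`, `t_statistic`, `t_p`, and the per-guide `scores`.
#' @export
validate_on_holdout <- function(holdout, table) {
  stopifnot(is.data.frame(holdout), all(c("sequence", "lfc") %in% names(holdout)))
  if (nrow(holdout) < 10L) stopf("holdout must contain >= 10 guides")
  sc <- score_guides(holdout$sequence, table)
  sc$lfc <- holdout$lfc
  ct <- suppressWarnings(
    stats::cor.test(sc$score, sc$lfc, method = "spearman", exact = FALSE))
  hi <- sc$lfc[sc$predicted_class == "high"]
  lo <- sc$lfc[sc$predicted_class == "low"]
  tt <- if (length(hi) >= 2L && length(lo) >= 2L) {
    stats::t.test(hi, lo, alternative = "two.sided")
  } else NULL
  list(n = nrow(sc),
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       mean_lfc_high = mean(hi), mean_lfc_low = mean(lo),
       t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       t_p = if (is.null(tt)) NA_real_ else tt$p.value,
       scores = sc)
}
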