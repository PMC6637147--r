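# Low Fat BAGEL: guide-level Bayes-factor essentiality classification for
# small libraries.
#
# The classic BAGEL workflow resamples reference *genes* across 1000
# permutations, which overfits when only a few hundred reference genes are
# available. This variant treats every reference guide as an independent
# observation: per permutation, ~60% of reference guides train
# kernel-density fold-change models for the essential and non-essential
# classes, and a log2 likelihood ratio (Bayes factor) is computed for every
# held-out reference guide and every non-reference guide. Guide BFs are
# averaged over permutations and summed per gene. For a multiplexed library
# with one construct per gene, the construct-level BF is the gene-level BF.

#' @noRd
kde_eval <- function(x, train, bw) {
  # Gaussian KDE evaluated at x: mean of N(x - t, bw) over training points
  if (length(x) == 0L) return(numeric(0))
  colMeans(matrix(stats::dnorm(outer(train, x, "-"), sd = bw),
                  nrow = length(train)))
}

#' Fit essential / non-essential fold-change densities
#'
#' Gaussian-kernel density estimates with the Silverman plug-in bandwidth
#' (`stats::bw.nrd0`). Evaluation is clamped to the interval where both
#' densities stay at or above `floor`, further bounded to
#' \[min(train) - 1, max(train) + 1\]; densities are floored before the
#' log-ratio so Bayes factors stay finite. When the two classes are so well
#' separated that no point clears the floor for both, the clamp interval
#' spans the two class modes instead, so the ratio saturates at either end.
#'
#' @param train_essential_lfc,train_nonessential_lfc training fold changes
#'   (log2), at least 20 values each.
#' @param floor density floor (default 1e-12).
#' @return a `DensityPair`.
#' @export
fit_densities <- function(train_essential_lfc, train_nonessential_lfc,
                          floor = 1e-12) {
  e <- train_essential_lfc
  n <- train_nonessential_lfc
  if (length(e) < 20L || length(n) < 20L) {
    stopf("need >= 20 training values per class (got %d, %d)",
          length(e), length(n))
  }
  if (stats::sd(e) == 0 || stats::sd(n) == 0) {
    stopf("degenerate (zero-variance) training set")
  }
  bw_e <- stats::bw.nrd0(e)
  bw_n <- stats::bw.nrd0(n)
  lo0 <- min(e, n) - 1
  hi0 <- max(e, n) + 1
  grid <- seq(lo0, hi0, length.out = 2048L)
  fe <- kde_eval(grid, e, bw_e)
  fn <- kde_eval(grid, n, bw_n)
  ok <- fe >= floor & fn >= floor
  if (any(ok)) {
    lfc_lo <- min(grid[ok])
    lfc_hi <- max(grid[ok])
  } else {
    # classes so well separated that no point clears the floor for both:
    # clamp to the interval between the two class modes, where the
    # (floored) likelihood ratio saturates at either end
    lfc_lo <- min(grid[which.max(fe)], grid[which.max(fn)])
    lfc_hi <- max(grid[which.max(fe)], grid[which.max(fn)])
  }
  structure(list(train_essential = e, train_nonessential = n,
                 bw_essential = bw_e, bw_nonessential = bw_n,
                 floor = floor, lfc_lo = lfc_lo, lfc_hi = lfc_hi),
            class = "DensityPair")
}

#' Guide-level Bayes factor
#'
#' BF = log2 of the ratio of the essential-class density to the
#' non-essential-class density at the guide's fold change, clamped to the
#' pair's evaluation interval and floored.
#'
#' @param lfc log2 fold change(s); vectorized.
#' @param dp a [fit_densities()] result.
#' @return Bayes factor(s), log2 units.
#' @export
guide_bf <- function(lfc, dp) {
  stopifnot(inherits(dp, "DensityPair"))
  x <- pmin(pmax(lfc, dp$lfc_lo), dp$lfc_hi)
  fe <- pmax(kde_eval(x, dp$train_essential, dp$bw_essential), dp$floor)
  fn <- pmax(kde_eval(x, dp$train_nonessential, dp$bw_nonessential), dp$floor)
  log2(fe / fn)
}

#' Bootstrap scheme for the permutation loop
#'
#' @param n_permutations number of permutations (default 100).
#' @param train_fraction fraction of reference guides (per class) used for
#'   training in each permutation, sampled without replacement (default 0.60).
#' @param seed RNG seed.
#' @return a `BootstrapScheme`.
#' @export
bootstrap_scheme <- function(n_permutations = 100, train_fraction = 0.60,
                             seed = 1) {
  stopifnot(n_permutations >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 train_fraction = train_fraction, unit = "guide",
                 seed = as.integer(seed)),
            class = "BootstrapScheme")
}

#' Run Low Fat BAGEL
#'
#' Builds one fold-change observation per guide (a multiplexed construct's
#' guides all inherit the construct's replicate-averaged fold change at the
#' chosen timepoint), then runs the guide-level permutation loop: per
#' permutation, `train_fraction` of reference guides per class train the
#' densities; Bayes factors are computed for held-out reference guides and
#' all non-reference guides. Per-guide BF = mean over the permutations in
#' which the guide was scored; gene BF = sum of its guides' mean BFs.
#' Permutation assignments are re-drawn if any reference guide would never
#' be held out. Deterministic given `scheme$seed`.
#'
#' @param fc a `FoldChangeMatrix`.
#' @param library the `GuideLibrary`.
#' @param refs a `ReferenceSets`; at least 50 reference guides per class
#'   must be present in the library.
#' @param scheme a [bootstrap_scheme()].
#' @param timepoint timepoint for the fold-change observation (default:
#'   endpoint).
#' @return a `BayesFactorTable`: list with `guides` (guide_id, gene, lfc,
#'   bf, n_scored) and `genes` (gene, bf, n_guides), non-targeting
#'   constructs excluded from the gene table.
#' @export
run_lowfat_bagel <- function(fc, library, refs, scheme = bootstrap_scheme(),
                             timepoint = NULL) {
  stopifnot(inherits(fc, "FoldChangeMatrix"), inherits(refs, "ReferenceSets"),
            inherits(scheme, "BootstrapScheme"))
  lfc_c <- replicate_mean_lfc(fc, timepoint)
  g <- library$guides[library$guides$construct_id %in% names(lfc_c), ]
  obs <- data.frame(
    guide_id = paste0(g$construct_id, ":", g$cistron),
    construct_id = g$construct_id,
    gene = g$gene,
    lfc = as.numeric(lfc_c[g$construct_id]),
    stringsAsFactors = FALSE
  )
  obs$class <- ifelse(obs$gene %in% refs$essential, "essential",
                      ifelse(obs$gene %in% refs$non_essential,
                             "nonessential", "unknown"))
  idx_e <- which(obs$class == "essential")
  idx_n <- which(obs$class == "nonessential")
  if (length(idx_e) < 50L || length(idx_n) < 50L) {
    stopf("need >= 50 reference guides per class in the library (got %d essential, %d non-essential)",
          length(idx_e), length(idx_n))
  }
  idx_u <- which(obs$class == "unknown")

  n_tr_e <- round(scheme$train_fraction * length(idx_e))
  n_tr_n <- round(scheme$train_fraction * length(idx_n))

  with_seed(scheme$seed, {
    # draw all permutation training sets up front; re-draw the whole plan if
    # some reference guide is never held out
    for (attempt in seq_len(100L)) {
      plan <- lapply(seq_len(scheme$n_permutations), function(p) {
        list(e = sample(idx_e, n_tr_e), n = sample(idx_n, n_tr_n))
      })
      held_out <- rep(FALSE, nrow(obs))
      for (p in plan) {
        held_out[setdiff(idx_e, p$e)] <- TRUE
        held_out[setdiff(idx_n, p$n)] <- TRUE
      }
      if (all(held_out[c(idx_e, idx_n)])) break
      if (attempt == 100L) {
        stopf("could not cover every reference guide in a test split; increase n_permutations")
      }
    }

    bf_sum <- rep(0, nrow(obs))
    n_scored <- rep(0L, nrow(obs))
    for (p in plan) {
      dp <- fit_densities(obs$lfc[p$e], obs$lfc[p$n])
      test <- c(setdiff(idx_e, p$e), setdiff(idx_n, p$n), idx_u)
      bf_sum[test] <- bf_sum[test] + guide_bf(obs$lfc[test], dp)
      n_scored[test] <- n_scored[test] + 1L
    }
    obs$bf <- ifelse(n_scored > 0L, bf_sum / pmax(n_scored, 1L), NA_real_)
    obs$n_scored <- n_scored
  })

  gene_rows <- obs[obs$gene != NON_TARGETING, ]
  genes <- unique(gene_rows$gene)
  gene_tab <- data.frame(
    gene = genes,
    bf = as.numeric(tapply(gene_rows$bf, factor(gene_rows$gene, levels = genes),
                           sum)),
    n_guides = as.integer(tapply(gene_rows$bf,
                                 factor(gene_rows$gene, levels = genes),
                                 length)),
    stringsAsFactors = FALSE
  )
  gene_tab$class <- ifelse(gene_tab$gene %in% refs$essential, "essential",
                           ifelse(gene_tab$gene %in% refs$non_essential,
                                  "nonessential", "unknown"))
  structure(list(guides = obs, genes = gene_tab, scheme = scheme),
            class = "BayesFactorTable")
}

#' @export
print.BayesFactorTable <- function(x, ...) {
  cat(sprintf("BayesFactorTable: %d guides, %d genes (%d permutations)\n",
              nrow(x$guides), nrow(x$genes), x$scheme$n_permutations))
  invisible(x)
}

#' Call essentiality hits at a fixed FDR
#'
#' Genes are ranked by Bayes factor (descending); precision is computed on
#' reference genes only (essential = true positive, non-essential = false
#' positive). The BF threshold is the smallest BF at which reference
#' precision still reaches 1 - fdr; hits are all genes, reference or not,
#' at or above it.
#'
#' @param bft a `BayesFactorTable`.
#' @param refs a `ReferenceSets`.
#' @param fdr target false discovery rate (default 0.01).
#' @return list with `hits` (gene names), `threshold_bf`, `realized_fdr`
#'   (on reference genes at the threshold) and `fdr`.
#' @export
call_hits_at_fdr <- function(bft, refs, fdr = 0.01) {
  stopifnot(inherits(bft, "BayesFactorTable"), fdr > 0, fdr < 1)
  g <- bft$genes[order(-bft$genes$bf), ]
  is_ref <- g$class %in% c("essential", "nonessential")
  ref <- g[is_ref, ]
  if (nrow(ref) == 0L) stopf("no scored reference genes")
  tp <- cumsum(ref$class == "essential")
  prec <- tp / seq_len(nrow(ref))
  ok <- prec >= 1 - fdr
  if (!any(ok)) {
    warnf("reference precision never reaches %.3f; empty hit set", 1 - fdr)
    return(list(hits = character(0), threshold_bf = NA_real_,
                realized_fdr = NA_real_, fdr = fdr))
  }
  i <- max(which(ok))
  thr <- ref$bf[i]
  list(hits = g$gene[g$bf >= thr], threshold_bf = thr,
       realized_fdr = 1 - prec[i], fdr = fdr)
}
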