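# Precision-recall benchmarking of essentiality rankings.
#
# AUC here is average precision: the expectation under a uniformly random
# ranking equals the prevalence of positives, which for the 342-essential /
# 345-non-essential benchmark sets is 342/687 = 0.498 — the null baseline
# the mAUC/rmAUC metrics subtract.

#' Precision-recall curve over reference genes
#'
#' Only reference genes enter the curve (positives = essential, negatives =
#' non-essential); other scored genes are ignored. Ranking is by score
#' descending with ties grouped and the whole tie group scored at its end
#' (conservative). AUC is average precision: the sum over positives of the
#' precision at their rank, divided by the number of positives.
#'
#' @param scores named numeric vector (gene or construct -> Bayes factor or
#'   any monotone score). Every reference gene must be present.
#' @param refs a `ReferenceSets` (names must match the score names).
#' @param level label for the curve, `"gene"` or `"construct"`.
#' @return a `PRCurve`: list with `points` (recall, precision at each tie
#'   group), `auc`, `level`, `n_positive`, `n_negative`.
#' @export
pr_curve <- function(scores, refs, level = c("gene", "construct")) {
  level <- match.arg(level)
  stopifnot(inherits(refs, "ReferenceSets"))
  all_ref <- c(refs$essential, refs$non_essential)
  missing <- setdiff(all_ref, names(scores))
  if (length(missing)) {
    stopf("reference genes without scores: %s%s",
          paste(utils::head(missing, 5L), collapse = ", "),
          if (length(missing) > 5L) sprintf(" (+%d more)", length(missing) - 5L) else "")
  }
  s <- scores[all_ref]
  pos <- names(s) %in% refs$essential
  ord <- order(-s)                      # stable: input order breaks ties
  s <- s[ord]; pos <- pos[ord]
  P <- sum(pos)

  grp_end <- cumsum(rle(as.numeric(s))$lengths)
  cum_tp <- cumsum(pos)
  precision <- cum_tp[grp_end] / grp_end
  recall <- cum_tp[grp_end] / P
  tp_in_grp <- diff(c(0, cum_tp[grp_end]))
  auc <- sum(tp_in_grp * precision) / P

  structure(list(points = data.frame(recall = recall, precision = precision),
                 auc = auc, level = level,
                 n_positive = P, n_negative = sum(!pos)),
            class = "PRCurve")
}

#' @export
print.PRCurve <- function(x, ...) {
  cat(sprintf("PRCurve (%s-level): AUC = %.4f (%d positives, %d negatives)\n",
              x$level, x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Null PR-AUC (prevalence of positives)
#'
#' When a ranking carries no information, precision at any recall equals the
#' prevalence of positives, so the average-precision AUC equals
#' |essential| / (|essential| + |non-essential|) — 0.498 for the 342/345
#' benchmark sets.
#'
#' @param refs a `ReferenceSets`.
#' @return prevalence.
#' @export
null_auc <- function(refs) {
  stopifnot(inherits(refs, "ReferenceSets"))
  length(refs$essential) / (length(refs$essential) + length(refs$non_essential))
}

#' mAUC / rmAUC temporal separation series
#'
#' mAUC at a timepoint is its PR-AUC minus the null AUC; rmAUC is the mAUC
#' expressed as a percentage of the endpoint mAUC:
#' rmAUC_x = (AUC_x - null) / (AUC_end - null) x 100%. The endpoint is the
#' last element; its rmAUC is 100% by construction.
#'
#' @param aucs numeric vector of per-timepoint PR-AUCs, endpoint last;
#'   names (if any) are carried into the output.
#' @param null null AUC (prevalence), default 0.498 for the benchmark sets.
#' @return data.frame with `auc`, `mauc`, `rmauc` (percent).
#' @export
rmauc <- function(aucs, null = 0.498) {
  stopifnot(is.numeric(aucs), length(aucs) >= 1L)
  auc_end <- aucs[[length(aucs)]]
  if (auc_end <= null) {
    stopf("no endpoint separation: AUC_end (%.3f) <= null (%.3f)", auc_end, null)
  }
  out <- data.frame(auc = as.numeric(aucs),
                    mauc = as.numeric(aucs) - null,
                    rmauc = (as.numeric(aucs) - null) / (auc_end - null) * 100)
  rownames(out) <- names(aucs)
  out
}

#' Down-sample guides per gene and re-benchmark
#'
#' Emulates comparing libraries of different guide complements: per draw,
#' `guides_per_gene` guides are sampled without replacement within each
#' gene, gene BFs are re-summed from the sampled guides' mean BFs, and the
#' gene-level PR-AUC is recomputed. Genes with fewer guides are excluded
#' (with a warning) from both sampling and the curve.
#'
#' @param bft a `BayesFactorTable` with guide-level BFs.
#' @param refs a `ReferenceSets`.
#' @param guides_per_gene guides retained per gene.
#' @param n_draws number of random down-samplings (default 10).
#' @param seed RNG seed.
#' @return list with `aucs` (per draw), `mean_auc`, `excluded` genes.
#' @export
down_sample <- function(bft, refs, guides_per_gene, n_draws = 10, seed = 1) {
  stopifnot(inherits(bft, "BayesFactorTable"), inherits(refs, "ReferenceSets"),
            guides_per_gene >= 1, n_draws >= 1)
  g <- bft$guides[bft$guides$gene %in% c(refs$essential, refs$non_essential), ]
  n_per <- table(g$gene)
  excluded <- names(n_per)[n_per < guides_per_gene]
  if (length(excluded)) {
    warnf("%d genes with fewer than %d guides excluded from down-sampling",
          length(excluded), guides_per_gene)
  }
  keep <- !(g$gene %in% excluded)
  g <- g[keep, ]
  refs2 <- reference_sets(setdiff(refs$essential, excluded),
                          setdiff(refs$non_essential, excluded))
  by_gene <- split(seq_len(nrow(g)), g$gene)
  aucs <- with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      sampled <- unlist(lapply(by_gene, function(ix) {
        if (length(ix) == guides_per_gene) ix else sample(ix, guides_per_gene)
      }))
      bf <- tapply(g$bf[sampled], g$gene[sampled], sum)
      pr_curve(stats::setNames(as.numeric(bf), names(bf)), refs2)$auc
    }, numeric(1))
  })
  list(aucs = aucs, mean_auc = mean(aucs), excluded = excluded)
}
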