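test_that("Bayes factors track the normal likelihood ratio on separated classes", {
  set.seed(101)
  tr_e <- rnorm(20000, -3, 1)
  tr_n <- rnorm(20000, 0, 1)
  dp <- fit_densities(tr_e, tr_n)
  # equal-variance normals cross midway: BF ~ 0 at -1.5
  expect_lt(abs(guide_bf(-1.5, dp)), 0.1)
  # at the essential mode the ratio is phi(0)/phi(3): log2 = 4.5/ln 2 = 6.49
  # (KDE smoothing and tail noise shave a few tenths off the peak ratio)
  expect_lt(abs(guide_bf(-3, dp) - 6.492), 0.6)
  # monotone non-increasing in lfc where both classes are data-dense
  # (KDE tails beyond ~3.5 sigma are sample-starved and jitter)
  xs <- seq(-3, 0, length.out = 40)
  bf <- guide_bf(xs, dp)
  expect_true(all(diff(bf) <= 0.02))
  expect_gt(bf[1] - bf[40], 10)
})

test_that("identical training classes give a flat zero Bayes factor", {
  set.seed(7)
  tr <- rnorm(500)
  dp <- fit_densities(tr, tr)
  expect_equal(guide_bf(seq(-3, 3, by = 0.5), dp), rep(0, 13))
})

test_that("Bayes factors clamp outside the evaluation interval", {
  set.seed(8)
  dp <- fit_densities(rnorm(100, -2), rnorm(100, 0))
  expect_equal(guide_bf(-50, dp), guide_bf(dp$lfc_lo, dp))
  expect_equal(guide_bf(+50, dp), guide_bf(dp$lfc_hi, dp))
})

test_that("degenerate training sets are rejected", {
  expect_error(fit_densities(rnorm(10), rnorm(100)), ">= 20")
  expect_error(fit_densities(rep(1, 30), rnorm(30)), "zero-variance")
})

test_that("guide_bf matches a brute-force KDE log-ratio oracle", {
  set.seed(33)
  tr_e <- rnorm(60, -2.5, 1.2)
  tr_n <- rnorm(70, 0, 0.9)
  dp <- fit_densities(tr_e, tr_n)
  x <- runif(100, -6, 3)
  expect_lt(max(abs(guide_bf(x, dp) -
                      oracle_bf(x, tr_e, tr_n, dp$lfc_lo, dp$lfc_hi))), 1e-9)
})

run_sim_bagel <- function(cfg, scheme) {
  sim <- simulate_screen(cfg)
  fc <- log2_fold_change(sim$counts)
  list(sim = sim, bft = run_lowfat_bagel(fc, sim$library, sim$refs, scheme))
}

test_that("the permutation loop is deterministic and covers every reference guide", {
  cfg <- sim_config(n_essential = 40, n_nonessential = 40, seed = 6)
  sch <- bootstrap_scheme(25, seed = 10)
  r1 <- run_sim_bagel(cfg, sch)
  r2 <- run_sim_bagel(cfg, sch)
  expect_identical(r1$bft$guides, r2$bft$guides)
  is_ref <- r1$bft$guides$class != "unknown"
  expect_true(all(r1$bft$guides$n_scored[is_ref] >= 1L))
  expect_true(all(r1$bft$guides$n_scored[!is_ref] == 25L))
})

test_that("gene BFs are exactly the sum of their guides' mean BFs", {
  r <- run_sim_bagel(sim_config(n_essential = 30, n_nonessential = 30,
                                guides_per_gene = 3, seed = 14),
                     bootstrap_scheme(10, seed = 1))
  g <- r$bft$guides
  recomputed <- tapply(g$bf, g$gene, sum)
  expect_equal(r$bft$genes$bf, as.numeric(recomputed[r$bft$genes$gene]))
  # dropping one guide lowers the gene BF by exactly that guide's mean BF
  gene1 <- r$bft$genes$gene[1L]
  rows <- g[g$gene == gene1, ]
  expect_equal(sum(rows$bf[-1L]),
               r$bft$genes$bf[r$bft$genes$gene == gene1] - rows$bf[1L])
})

test_that("one construct per gene makes construct and gene BFs coincide", {
  r <- run_sim_bagel(sim_config(n_essential = 30, n_nonessential = 30,
                                guides_per_gene = 3, mode = "cpf1_multi",
                                seed = 4),
                     bootstrap_scheme(10, seed = 2))
  g <- r$bft$guides
  construct_bf <- tapply(g$bf, g$construct_id, sum)
  genes_of <- tapply(g$gene, g$construct_id, `[`, 1L)
  expect_equal(as.numeric(construct_bf),
               r$bft$genes$bf[match(genes_of, r$bft$genes$gene)])
})

test_that("strong dropout separates classes; label permutation destroys it", {
  cfg <- sim_config(n_essential = 60, n_nonessential = 60, p_active_guide = 1,
                    essential_lfc_mean = -2, essential_lfc_sd = 0.2, seed = 19)
  sim <- simulate_screen(cfg)
  fc <- log2_fold_change(sim$counts)
  bft <- run_lowfat_bagel(fc, sim$library, sim$refs, bootstrap_scheme(20, seed = 3))
  sc <- setNames(bft$genes$bf, bft$genes$gene)
  expect_gt(pr_curve(sc, sim$refs)$auc, 0.95)

  # shuffle the gene labels of the reference sets: BFs become uninformative
  set.seed(99)
  genes <- c(sim$refs$essential, sim$refs$non_essential)
  shuffled <- sample(genes)
  refs_null <- reference_sets(shuffled[seq_along(sim$refs$essential)],
                              shuffled[-seq_along(sim$refs$essential)])
  bft_null <- run_lowfat_bagel(fc, sim$library, refs_null,
                               bootstrap_scheme(20, seed = 3))
  w <- wilcox.test(bft_null$genes$bf[bft_null$genes$class == "essential"],
                   bft_null$genes$bf[bft_null$genes$class == "nonessential"])
  expect_gt(w$p.value, 0.01)
})

test_that("FDR hit calling keeps the realized reference FDR at or below target", {
  cfg <- sim_config(n_essential = 80, n_nonessential = 80, p_active_guide = 0.9,
                    essential_lfc_mean = -2, seed = 27)
  sim <- simulate_screen(cfg)
  fc <- log2_fold_change(sim$counts)
  bft <- run_lowfat_bagel(fc, sim$library, sim$refs, bootstrap_scheme(20, seed = 5))
  hits <- call_hits_at_fdr(bft, sim$refs, 0.05)
  expect_lte(hits$realized_fdr, 0.05)
  expect_gt(length(hits$hits), 40)
  # perfectly separated scores: hits are exactly the genes above every negative
  sep <- bft
  sep$genes$bf <- ifelse(sep$genes$class == "essential", 10, -10) +
    seq_len(nrow(sep$genes)) * 1e-3
  h2 <- call_hits_at_fdr(sep, sim$refs, 0.01)
  expect_setequal(h2$hits, sep$genes$gene[sep$genes$class == "essential"])
  # shuffled scores: empty or near-empty hit set
  shuf <- bft
  set.seed(1); shuf$genes$bf <- sample(shuf$genes$bf)
  h3 <- suppressWarnings(call_hits_at_fdr(shuf, sim$refs, 0.01))
  expect_lt(length(h3$hits), 10)
})

test_that("too few reference guides per class is an error", {
  cfg <- sim_config(n_essential = 10, n_nonessential = 10, seed = 3)
  sim <- simulate_screen(cfg)
  fc <- log2_fold_change(sim$counts)
  expect_error(run_lowfat_bagel(fc, sim$library, sim$refs), ">= 50")
})
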