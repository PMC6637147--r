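# cpf1screen

Analysis and design of pooled CRISPR knockout screens built on AsCpf1
(Cas12a). AsCpf1 processes its own crRNA, so one lentiviral construct can
carry an *array* of guides — all the guides for one gene on a single
vector — which shrinks a whole-genome knockout library to one construct
per gene. This package is for people running or designing such screens:
it benchmarks multiplexed libraries against gold-standard essential /
non-essential gene sets, classifies gene essentiality from read counts,
learns AsCpf1's protospacer sequence preferences from screen data, and
designs new multiplexed libraries from a genome.

## What's inside

* **Screen model & I/O** — validated TSV readers/writers for guide
  libraries (mono-cistronic or multiplexed, ragged 1–7 guide arrays),
  read-count matrices with per-replicate reference samples, and reference
  gene sets.
* **Fold change** — depth normalization (default scale 10⁷, pseudocount
  0.5) and log2 fold change of each sample against its replicate's
  reference.
* **Active-construct calling** — an essential-targeting construct is
  *active* if its fold change falls below the lower-tail FPR quantile
  (default 5%) of the non-essential constructs, per replicate and
  timepoint.
* **Low Fat BAGEL** — a small-library Bayes-factor essentiality
  classifier: per permutation (default 100), 60% of reference *guides*
  train kernel-density fold-change models for the two classes; each guide's
  Bayes factor BF = log2 f̂\_ess(x)/f̂\_non(x) is averaged over held-out
  permutations and summed per gene; hits are called at a target FDR on the
  reference-gene precision.
* **PR metrics** — precision-recall curves and average-precision AUC over
  reference genes; the null AUC equals the prevalence of positives
  (342/687 = 0.498 for the benchmark sets); mAUC = AUC − 0.498 and
  rmAUC\_x = (AUC\_x − 0.498)/(AUC\_end − 0.498) × 100% track how fast
  class separation develops; guide down-sampling re-benchmarks smaller
  complements.
* **Guide scoring** — per essential gene, the most/least depleted guides
  define high/low performers; bootstrapped per-position nucleotide
  frequency differences (high − low) give a 4 × 20 preference matrix; a
  guide's score is the sum of its positional cells, score > 0 predicting a
  high performer; median guides validate the matrix.
* **Library design** — TTTV-PAM scanning of both strands, homopolymer and
  BsmBI filters, exhaustive mismatch-tolerant off-target counting by
  annotation class (exonic/intronic/intergenic), lexicographic guide
  ranking, crRNA array assembly (DR–guide–DR–guide…), genomic span of an
  array's cut sites, and combinatorial sizing of pairwise-perturbation
  libraries (1000 genes × 6 perturbagens: 36 M mono-cistronic vectors vs
  1 M multiplexed).
* **Screen simulator** — negative-binomial counts around log-normal
  reference abundances with per-guide Bernoulli activity and a constant
  log2 dropout rate for active essential-targeting guides; optional planted
  sequence motifs; full planted truth returned for validation.

## Worked example

Simulate a benchmark-style screen (342 essential + 345 non-essential genes,
three guides per gene on one multiplexed construct each, four timepoints in
triplicate) and push it through the full pipeline:

```r
library(cpf1screen)

sim <- simulate_screen(sim_config(seed = 42))
summarize_library(sim$library)
#> constructs: 687 | guides: 2061 | genes: 687 | non-targeting: 0
#> guides/construct: 687x3

fc <- log2_fold_change(sim$counts)
active_fraction(fc, sim$library, sim$refs, fpr = 0.05)
#> Active constructs at FPR 5%:
#>   T1: 32.7% +/- 2.3%
#>   T2: 65.3% +/- 1.7%
#>   T3: 70.3% +/- 1.8%
#>   T4: 70.7% +/- 1.8%
```

The active fraction climbs from ~33% to a ~70% plateau: with per-guide
activity 0.317 and three independent guides per construct, the chance a
construct carries at least one functional guide is 1 − (1 − 0.317)³ ≈ 0.68
— the multiplexing advantage over a one-guide-per-vector library.

```r
bft <- run_lowfat_bagel(fc, sim$library, sim$refs,
                        bootstrap_scheme(100, seed = 1))
pr_curve(setNames(bft$genes$bf, bft$genes$gene), sim$refs)
#> PRCurve (gene-level): AUC = 0.8921 (342 positives, 345 negatives)

hits <- call_hits_at_fdr(bft, sim$refs, fdr = 0.01)
length(hits$hits)
#> [1] 239

rmauc(c(0.498, 0.700, 0.900), null = 0.498)
#>     auc  mauc     rmauc
#> 1 0.498 0.000   0.00000
#> 2 0.700 0.202  50.24876
#> 3 0.900 0.402 100.00000
```

The PR-AUC of 0.89 against 0.498 for an uninformative ranking says the
Bayes-factor ranking separates the classes well even though ~30% of
constructs carry no functional guide; 239 genes clear the 1% FDR
threshold. The `rmauc` table shows the temporal-separation metric's two
identities (0% at the null, 100% at the endpoint) and the intermediate
point at 50.2%.

A command-line front end wrapping these functions (plus the designer) is
installed at `inst/cli/cpf1screen.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cpf1screen.R", package="cpf1screen"))')" \
    simulate --out-dir sim/ --seed 7
```

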