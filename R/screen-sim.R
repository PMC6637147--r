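# Synthetic pooled-screen generator.
#
# Emulates the statistical structure a dropout screen analysis assumes:
# log-normal cloning skew around a target depth, per-guide Bernoulli
# activity, a constant per-timepoint log2 dropout rate for active
# essential-targeting guides, and negative-binomial sequencing noise.
# Every downstream stage of the package is testable against the planted
# truth with no external data.

#' Simulation configuration
#'
#' Defaults emulate the benchmark screen design: 342 core-essential and 345
#' non-essential genes, three guides per gene on one multiplexed AsCpf1
#' construct each, four timepoints in triplicate with one reference sample
#' per replicate. The default per-guide activity probability 0.317 is the
#' mono-cistronic AsCpf1 active-construct fraction, read as a per-guide
#' activity proxy.
#'
#' @param n_essential,n_nonessential number of essential / non-essential genes.
#' @param guides_per_gene guides per gene (all on one construct in
#'   `cpf1_multi` mode; one construct each in the mono modes).
#' @param mode nuclease/library mode, see [guide_library()].
#' @param p_active_guide probability a guide is functional.
#' @param essential_lfc_mean,essential_lfc_sd log2 dropout effect per active
#'   essential-targeting guide per timepoint unit (mean must be <= 0).
#' @param timepoints integer timepoints sampled (reference is timepoint 0).
#' @param replicates number of replicates.
#' @param depth_mean mean reads per construct in the reference sample.
#' @param nb_dispersion negative-binomial size parameter (variance =
#'   mu + mu^2/size; large values approach Poisson).
#' @param lognormal_sd s.d. (log2 units) of the cloning-skew log-normal on
#'   reference abundances.
#' @param motif optional planted positional activity motif: named character
#'   vector, names are protospacer positions 1..20, values the favored base,
#'   e.g. `c("1" = "G", "3" = "T")`. Guides matching more motif positions are
#'   more likely to be active.
#' @param motif_effect log-odds of activity added per matched motif position
#'   (centered at the chance expectation of 1/4 matches).
#' @param seed RNG seed.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_essential = 342, n_nonessential = 345,
                       guides_per_gene = 3,
                       mode = c("cpf1_multi", "cpf1_mono", "cas9_mono"),
                       p_active_guide = 0.317,
                       essential_lfc_mean = -1, essential_lfc_sd = 0.3,
                       timepoints = 1:4, replicates = 3,
                       depth_mean = 500, nb_dispersion = 10,
                       lognormal_sd = 0.5,
                       motif = NULL, motif_effect = 2, seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(n_essential = as.integer(n_essential),
              n_nonessential = as.integer(n_nonessential),
              guides_per_gene = as.integer(guides_per_gene),
              mode = mode, p_active_guide = p_active_guide,
              essential_lfc_mean = essential_lfc_mean,
              essential_lfc_sd = essential_lfc_sd,
              timepoints = as.integer(timepoints),
              replicates = as.integer(replicates),
              depth_mean = depth_mean, nb_dispersion = nb_dispersion,
              lognormal_sd = lognormal_sd,
              motif = motif, motif_effect = motif_effect,
              seed = as.integer(seed))
  if (cfg$p_active_guide < 0 || cfg$p_active_guide > 1) {
    stopf("p_active_guide must be in [0, 1]")
  }
  if (cfg$essential_lfc_mean > 0) stopf("essential_lfc_mean must be <= 0")
  if (cfg$depth_mean <= 0) stopf("depth_mean must be > 0")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (cfg$guides_per_gene < 1) stopf("guides_per_gene must be >= 1")
  if (!is.null(motif)) {
    stopifnot(all(motif %in% c("A", "C", "G", "T")),
              all(as.integer(names(motif)) %in% 1:20))
  }
  structure(cfg, class = "SimConfig")
}

#' Expected fraction of constructs with at least one active guide
#'
#' With per-guide activity probability p and k independent guides per
#' construct, the chance that a construct carries at least one functional
#' guide is 1 - (1 - p)^k — the multiplexing advantage of crRNA arrays.
#'
#' @param p_active_guide per-guide activity probability.
#' @param guides_per_construct guides per construct.
#' @return probability.
#' @examples
#' expected_active_fraction(0.317, 1)  # mono-cistronic
#' expected_active_fraction(0.5, 3)    # 0.875
#' @export
expected_active_fraction <- function(p_active_guide, guides_per_construct) {
  stopifnot(p_active_guide >= 0, p_active_guide <= 1, guides_per_construct >= 1)
  1 - (1 - p_active_guide)^guides_per_construct
}

#' @noRd
random_guides <- function(n) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * 20L, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate a pooled dropout screen
#'
#' Reference abundances per construct are log-normal around `depth_mean`
#' (rescaled so their expectation is exactly `depth_mean`). Each guide is
#' active with probability `p_active_guide` (optionally modulated by a
#' planted sequence motif); an active guide targeting an essential gene
#' carries a log2 effect per timepoint unit drawn from
#' N(`essential_lfc_mean`, `essential_lfc_sd`). A construct's effect is that
#' of its strongest active guide (the minimum, i.e. most-depleting, over its
#' guides). Counts are negative binomial around
#' abundance x 2^(effect x timepoint). Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `library` (`GuideLibrary`), `counts` (`CountMatrix`),
#'   `refs` (`ReferenceSets`) and `truth` (per-guide and per-construct
#'   planted effects).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  n_genes <- cfg$n_essential + cfg$n_nonessential
  if (n_genes == 0L) stopf("degenerate config: 0 genes")
  with_seed(cfg$seed, {
    genes <- c(sprintf("ESS%04d", seq_len(cfg$n_essential)),
               sprintf("NON%04d", seq_len(cfg$n_nonessential)))
    essential <- rep(c(TRUE, FALSE), c(cfg$n_essential, cfg$n_nonessential))
    k <- cfg$guides_per_gene

    gene_of_guide <- rep(genes, each = k)
    ess_of_guide <- rep(essential, each = k)
    cistron <- rep(seq_len(k), times = n_genes)
    seqs <- random_guides(n_genes * k)

    if (cfg$mode == "cpf1_multi") {
      constr_of_guide <- paste0(gene_of_guide, "_arr")
    } else {
      constr_of_guide <- paste0(gene_of_guide, "_g", cistron)
      cistron <- rep(1L, length(cistron))
    }

    # per-guide activity, optionally motif-modulated
    p <- rep(cfg$p_active_guide, length(seqs))
    if (!is.null(cfg$motif) && length(cfg$motif)) {
      pos <- as.integer(names(cfg$motif))
      chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
      matches <- rowSums(chars[, pos, drop = FALSE] ==
                           matrix(cfg$motif, nrow = length(seqs),
                                  ncol = length(pos), byrow = TRUE))
      p <- stats::plogis(stats::qlogis(pmin(pmax(cfg$p_active_guide, 1e-6),
                                            1 - 1e-6)) +
                           cfg$motif_effect * (matches - length(pos) / 4))
    }
    active <- stats::runif(length(seqs)) < p
    guide_effect <- ifelse(active & ess_of_guide,
                           stats::rnorm(length(seqs), cfg$essential_lfc_mean,
                                        cfg$essential_lfc_sd),
                           0)

    lib <- guide_library(data.frame(construct_id = constr_of_guide,
                                    gene = gene_of_guide, cistron = cistron,
                                    sequence = seqs, stringsAsFactors = FALSE),
                         cfg$mode)
    ids <- construct_ids(lib)
    # construct effect = strongest (most negative) active guide
    constr_effect <- tapply(guide_effect, factor(constr_of_guide, levels = ids),
                            min)

    # reference abundances: log-normal, rescaled to mean exactly depth_mean
    z <- stats::rnorm(length(ids), 0, cfg$lognormal_sd)
    abund <- cfg$depth_mean * 2^z / exp((cfg$lognormal_sd * log(2))^2 / 2)

    labels <- unlist(lapply(seq_len(cfg$replicates), function(r) {
      c(sprintf("T0_ref_R%d", r), sprintf("T%d_R%d", cfg$timepoints, r))
    }))
    samples <- parse_sample_labels(labels)
    counts <- matrix(0L, nrow = length(ids), ncol = length(labels),
                     dimnames = list(ids, labels))
    for (j in seq_along(labels)) {
      t <- samples$timepoint[j]
      mu <- abund * 2^(constr_effect * t)
      counts[, j] <- stats::rnbinom(length(ids), mu = mu,
                                    size = cfg$nb_dispersion)
    }

    truth <- list(
      guides = data.frame(construct_id = constr_of_guide,
                          gene = gene_of_guide, cistron = cistron,
                          sequence = seqs, essential = ess_of_guide,
                          active = active, effect = guide_effect,
                          stringsAsFactors = FALSE),
      constructs = data.frame(construct_id = ids,
                              gene = construct_genes(lib)[ids],
                              essential = tapply(ess_of_guide,
                                                 factor(constr_of_guide,
                                                        levels = ids),
                                                 `[`, 1L),
                              effect = as.numeric(constr_effect),
                              abundance = abund,
                              stringsAsFactors = FALSE)
    )
    list(library = lib,
         counts = count_matrix(counts, samples),
         refs = reference_sets(genes[essential], genes[!essential]),
         truth = truth)
  })
}
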