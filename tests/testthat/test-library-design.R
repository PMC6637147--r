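# Background strings deliberately free of TTTV/BAAA PAM sites so planted
# sites are the only candidates: alternating purine/pyrimidine with no T or
# A runs.
quiet_bg <- function(len) {
  paste(rep_len(strsplit("ACGC", "")[[1]], len), collapse = "")
}

test_that("a literal 25-nt sequence yields exactly one forward candidate", {
  g <- c(chr1 = "TTTACCCCGGGGAAAATTTTCCCCG")
  cands <- scan_pams(g)
  fwd <- cands[cands$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$pam_start, 0L)
  expect_equal(fwd$pam, "TTTA")
  expect_equal(fwd$protospacer, "CCCCGGGGAAAATTTTCCCC")
})

test_that("TTTT is not a valid PAM and short sequences yield no candidates", {
  g <- c(chr1 = paste0("TTTT", quiet_bg(20)))
  cands <- scan_pams(g)
  expect_false(any(substr(cands$pam, 4, 4) == "T"))
  expect_equal(nrow(scan_pams(c(chr1 = "TTTACGT"))), 0L)
})

test_that("a sequence and its reverse complement give mirrored candidates", {
  set.seed(80)
  s <- rand_chrom(2000)
  c1 <- scan_pams(c(chr1 = s))
  c2 <- scan_pams(c(chr1 = revcomp(s)))
  expect_equal(nrow(c1), nrow(c2))
  expect_setequal(c1$protospacer, c2$protospacer)
  # a + candidate at pam_start p maps to a - candidate at L - p - 4
  p1 <- sort(c1$pam_start[c1$strand == "+"])
  p2 <- sort(2000 - c2$pam_start[c2$strand == "-"] - 4)
  expect_equal(p1, p2)
})

test_that("scan_pams equals a brute-force regex oracle on random 10 kb genomes", {
  set.seed(81)
  for (i in 1:2) {
    g <- c(chrA = rand_chrom(10000), chrB = rand_chrom(3000))
    got <- scan_pams(g)
    want <- oracle_scan(g)
    key <- function(d) sort(paste(d$chrom, d$pam_start, d$strand, d$pam,
                                  d$protospacer))
    expect_identical(key(got), key(want))
  }
})

test_that("candidates overlapping N are dropped", {
  g <- c(chr1 = paste0("TTTA", "ACGTACGTNNGTACGTACGT", quiet_bg(10)))
  expect_equal(nrow(scan_pams(g)[scan_pams(g)$strand == "+", ]), 0L)
})

test_that("homopolymer and BsmBI filters follow the documented rules", {
  cands <- data.frame(
    protospacer = c("ACGTTTTACGTACGTACGTA",    # T-run of 4
                    "ACGAAAAACGTACGTACGTA",    # A-run of 5
                    "ACGAAAACGTACGTACGTAC",    # A-run of 4: allowed
                    "ACGTCGTCTCGTACGTACGT",    # BsmBI site
                    "ACGTGAGACGGTACGTACGT",    # BsmBI reverse complement
                    "ACGTACGTACGTACGTACGT"),   # clean
    stringsAsFactors = FALSE)
  out <- filter_candidates(cands)
  expect_equal(out$fail_homopolymer, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$fail_bsmbi, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$pass, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

planted_genome <- function(cand_proto, dup1, dup2 = NULL, dup2_pam = "TTTA") {
  # candidate at a known locus plus planted near-duplicates downstream
  paste0(quiet_bg(40), "TTTA", cand_proto,
         quiet_bg(40), "TTTA", dup1,
         if (!is.null(dup2)) paste0(quiet_bg(40), dup2_pam, dup2) else "",
         quiet_bg(40))
}

test_that("planted duplicates are counted by class; tolerance boundaries hold", {
  proto <- "ACGCAGTCAGGACGCAGGAC"     # no internal PAM sites
  mm1 <- proto; substr(mm1, 20, 20) <- "T"           # 1 mismatch at pos 20
  mm2 <- proto; substr(mm2, 19, 19) <- "T"; substr(mm2, 20, 20) <- "T"
  g <- c(chr1 = planted_genome(proto, mm1, mm2))
  cands <- scan_pams(g)
  cand <- cands[cands$pam_start == 40L & cands$strand == "+", ]
  expect_equal(nrow(cand), 1L)
  # dup1's protospacer occupies [108, 128): its midpoint 118 is exonic
  ann <- data.frame(chrom = "chr1", start = 100L, end = 130L, class = "exonic",
                    stringsAsFactors = FALSE)

  # minihuman: whole 20-mer, <=1 mismatch: the 1-mm duplicate (exonic) hits,
  # the 2-mm duplicate does not
  mh <- count_offtargets(cand, g, ann, offtarget_policy("minihuman"))
  expect_equal(mh$ot_exonic, 1L)
  expect_equal(mh$ot_intronic, 0L)
  expect_equal(mh$ot_total, 1L)

  # benchmark: PAM-adjacent 18 nt only, so both duplicates (mismatches at
  # 19/20) are distance 0 and both count
  bm <- count_offtargets(cand, g, ann, offtarget_policy("benchmark"))
  expect_equal(bm$ot_exonic, 1L)
  expect_equal(bm$ot_intergenic, 1L)  # dup2 midpoint lies outside the exon
  expect_equal(bm$ot_total, 2L)
})

test_that("a duplicate without a valid PAM is never a hit", {
  proto <- "ACGCAGTCAGGACGCAGGAC"
  g <- c(chr1 = planted_genome(proto, dup1 = proto, dup2 = proto,
                               dup2_pam = "TTTT"))
  cands <- scan_pams(g)
  cand <- cands[cands$pam_start == 40L & cands$strand == "+", ]
  mh <- count_offtargets(cand, g, NULL, offtarget_policy("minihuman"))
  expect_equal(mh$ot_total, 1L)   # only the TTTA-fronted exact duplicate
})

test_that("count_offtargets equals a brute-force Hamming oracle on random genomes", {
  set.seed(83)
  g <- c(chrA = rand_chrom(10000))
  ann <- data.frame(chrom = "chrA",
                    start = c(1000L, 4000L), end = c(2500L, 6000L),
                    class = c("exonic", "intronic"), stringsAsFactors = FALSE)
  sites <- scan_pams(g)
  pick <- sites[sample(nrow(sites), 4L), ]
  for (mode in c("minihuman", "benchmark")) {
    pol <- offtarget_policy(mode)
    got <- count_offtargets(pick, g, ann, pol)
    for (i in seq_len(nrow(pick))) {
      want <- oracle_offtargets(pick[i, ], g, ann, pol$positions,
                                pol$max_mismatches)
      expect_equal(c(got$ot_exonic[i], got$ot_intronic[i], got$ot_intergenic[i]),
                   unname(want))
    }
  }
})

test_that("guide selection ranks lexicographically and applies exclusions", {
  base <- data.frame(
    protospacer = rand_seqs(5), pass = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    ot_exonic = 0L, ot_intronic = 0L,
    ot_intergenic = c(2L, 0L, 0L, 0L, 0L),
    target_transcripts = c(3L, 3L, 3L, 3L, 2L),
    sequence_score = c(0.5, 0.2, 0.9, 1.0, 1.0),
    distance_to_first_exon = c(10L, 5L, 500L, 1L, 1L),
    stringsAsFactors = FALSE)
  base$ot_total <- base$ot_intergenic
  sel <- select_guides(base, k = 4, policy = offtarget_policy("minihuman"))
  # filter-failing row 4 removed; transcripts desc, then intergenic asc,
  # then score desc, then distance asc
  expect_equal(rownames(sel), c("3", "2", "1", "5"))
  # minihuman exclusion: any exonic/intronic off-target removes a candidate
  base2 <- base; base2$ot_intronic[2] <- 1L
  sel2 <- select_guides(base2, k = 4, policy = offtarget_policy("minihuman"))
  expect_false("2" %in% rownames(sel2))
  # benchmark exclusion: more than 2 total off-targets
  base3 <- base; base3$ot_total[1] <- 3L
  sel3 <- select_guides(base3, k = 4, policy = offtarget_policy("benchmark"))
  expect_false("1" %in% rownames(sel3))
})

test_that("arrays assemble as alternating DR-spacer oligos within limits", {
  guides <- rand_seqs(4)
  arr <- build_array("MYC", guides, direct_repeat = default_direct_repeat())
  expect_equal(nchar(arr$oligo), 4 * (19 + 20))
  expect_equal(arr$oligo,
               paste0(paste0(default_direct_repeat(), guides), collapse = ""))
  one <- build_array("MYC", guides[1])
  expect_equal(nchar(one$oligo), 39)
  expect_error(build_array("MYC", character()), "empty")
  expect_error(build_array("MYC", rand_seqs(8)), "limit")
})

test_that("combinatorial sizing reproduces the pairwise-library arithmetic", {
  expect_equal(combinatorial_size(1000, 6, 2, "mono_pairwise"), 36e6)
  expect_equal(combinatorial_size(1000, 6, 2, "multiplexed"), 1e6)
  expect_equal(combinatorial_size(1, 4, 2, "multiplexed"), 1)
  expect_error(combinatorial_size(10, 2, 3, "multiplexed"), "arity")
})

test_that("array span is the cut-site range, undefined across chromosomes", {
  same <- data.frame(chrom = "chr1", pam_start = c(100L, 100L), strand = "+")
  expect_equal(array_span(same)$span, 0)
  two <- data.frame(chrom = "chr1", pam_start = c(100L, 3100L), strand = "+")
  expect_equal(array_span(two)$span, 3000)
  mixed <- data.frame(chrom = c("chr1", "chr2"), pam_start = c(1L, 2L),
                      strand = "+")
  expect_false(array_span(mixed)$defined)
})

test_that("the end-to-end designer matches an independent ranking on a toy genome", {
  set.seed(85)
  n_genes <- 8
  gene_len <- 600
  chrom <- rand_chrom(n_genes * gene_len + 500)
  g <- c(chr1 = chrom)
  ann <- data.frame(chrom = "chr1",
                    start = (seq_len(n_genes) - 1L) * gene_len,
                    end = seq_len(n_genes) * gene_len - 100L,
                    class = "exonic",
                    gene = sprintf("G%02d", seq_len(n_genes)),
                    transcript_count = 1L,
                    first_exon_start = (seq_len(n_genes) - 1L) * gene_len,
                    stringsAsFactors = FALSE)
  d <- design_library(g, ann, guides_per_gene = 4, min_guides = 1,
                      policy = offtarget_policy("minihuman"))
  expect_s3_class(d$library, "GuideLibrary")
  expect_true(all(summarize_library(d$library)$guides_per_construct |>
                    names() |> as.integer() <= 4))

  # independent reconstruction: oracle scan + filters + oracle off-targets,
  # ranked by the documented lexicographic order
  sites <- oracle_scan(g)
  pol <- offtarget_policy("minihuman")
  for (gn in names(d$arrays)[1:3]) {
    row <- ann[ann$gene == gn, ]
    lo <- ifelse(sites$strand == "+", sites$pam_start + 4L,
                 sites$pam_start - 20L)
    mid <- lo + 10L
    mine <- sites[sites$chrom == "chr1" & row$start <= mid & mid < row$end, ]
    keep <- !grepl("T{4,}|A{5,}|C{5,}|G{5,}|CGTCTC|GAGACG", mine$protospacer)
    mine <- mine[keep, ]
    mine <- mine[order(mine$pam_start, mine$strand), ]   # match scan order
    ot <- t(vapply(seq_len(nrow(mine)), function(i) {
      oracle_offtargets(mine[i, ], g, ann, pol$positions, pol$max_mismatches)
    }, numeric(3)))
    mine <- mine[ot[, "exonic"] + ot[, "intronic"] == 0, ]
    ot <- ot[ot[, "exonic"] + ot[, "intronic"] == 0, , drop = FALSE]
    fes <- row$first_exon_start
    lo_m <- ifelse(mine$strand == "+", mine$pam_start + 4L, mine$pam_start - 20L)
    ord <- order(ot[, "intergenic"], abs(lo_m + 10L - fes))
    expected <- mine$protospacer[ord][seq_len(min(4L, nrow(mine)))]
    expect_equal(d$arrays[[gn]]$guides, expected)
  }
})
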