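# Fixture builders and independent brute-force oracles used across tests.

rand_seqs <- function(n, len = 20L) {
  do.call(paste0, lapply(seq_len(len), function(i) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  }))
}

rand_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

make_mono_library <- function(genes, guides_per_gene = 3L, mode = "cpf1_mono",
                              seqs = NULL) {
  n <- length(genes) * guides_per_gene
  if (is.null(seqs)) seqs <- rand_seqs(n)
  guide_library(data.frame(
    construct_id = paste0(rep(genes, each = guides_per_gene), "_g",
                          rep(seq_len(guides_per_gene), length(genes))),
    gene = rep(genes, each = guides_per_gene),
    cistron = 1L, sequence = seqs, stringsAsFactors = FALSE), mode)
}

# FoldChangeMatrix built directly from an lfc matrix (colnames = sample labels)
make_fc <- function(lfc) {
  structure(list(lfc = lfc, samples = parse_sample_labels(colnames(lfc))),
            class = "FoldChangeMatrix")
}

# ---- independent oracles ----------------------------------------------------

# average precision for distinct scores: straight loop over ranked positives
oracle_ap <- function(scores, is_positive) {
  ord <- order(-scores)
  lab <- is_positive[ord]
  sum(vapply(which(lab), function(r) mean(lab[seq_len(r)]), numeric(1))) /
    sum(lab)
}

# Gaussian KDE log2 ratio with floor and clamp, explicit per-point loops
oracle_bf <- function(x, tr_e, tr_n, lo, hi, floor = 1e-12) {
  vapply(x, function(xx) {
    xx <- min(max(xx, lo), hi)
    fe <- 0; for (t in tr_e) fe <- fe + dnorm(xx - t, sd = bw.nrd0(tr_e))
    fn <- 0; for (t in tr_n) fn <- fn + dnorm(xx - t, sd = bw.nrd0(tr_n))
    log2(max(fe / length(tr_e), floor) / max(fn / length(tr_n), floor))
  }, numeric(1))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), character(1)))
}

# Regex scan for TTTV protospacer candidates. The minus strand is found
# directly on the forward sequence as <20-mer>[TCG]AAA (the reverse
# complement of TTTV lies 3' of the reverse-complemented protospacer), so no
# coordinate mirroring arithmetic is shared with the implementation.
oracle_scan <- function(genome) {
  out <- list()
  for (chrom in names(genome)) {
    seqstr <- genome[[chrom]]
    L <- nchar(seqstr)
    m <- gregexpr("(?=TTT[ACG])", seqstr, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      q <- as.integer(m)
      q <- q[q + 23L <= L]
      if (length(q)) {
        proto <- substring(seqstr, q + 4L, q + 23L)
        keep <- !grepl("[^ACGT]", proto)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pam_start = q[keep] - 1L, strand = "+",
          pam = substring(seqstr, q, q + 3L)[keep],
          protospacer = proto[keep], stringsAsFactors = FALSE)
      }
    }
    m <- gregexpr("(?=[TCG]AAA)", seqstr, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      q <- as.integer(m)
      q <- q[q - 20L >= 1L]
      if (length(q)) {
        fwd20 <- substring(seqstr, q - 20L, q - 1L)
        keep <- !grepl("[^ACGT]", fwd20)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pam_start = q[keep] - 1L, strand = "-",
          pam = revcomp(substring(seqstr, q, q + 3L)[keep]),
          protospacer = revcomp(fwd20[keep]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Hamming off-target counts by class via explicit loops over oracle sites
oracle_offtargets <- function(cand, genome, annotation, positions, max_mm) {
  sites <- oracle_scan(genome)
  counts <- c(exonic = 0L, intronic = 0L, intergenic = 0L)
  for (i in seq_len(nrow(sites))) {
    if (sites$chrom[i] == cand$chrom && sites$pam_start[i] == cand$pam_start &&
        sites$strand[i] == cand$strand) next
    a <- strsplit(sites$protospacer[i], "")[[1L]]
    b <- strsplit(cand$protospacer, "")[[1L]]
    mm <- 0L
    for (p in positions) if (a[p] != b[p]) mm <- mm + 1L
    if (mm > max_mm) next
    lo <- if (sites$strand[i] == "+") sites$pam_start[i] + 4L else
      sites$pam_start[i] - 20L
    mid <- lo + 10L
    cls <- "intergenic"
    if (!is.null(annotation)) {
      ov <- annotation$chrom == sites$chrom[i] & annotation$start <= mid &
        mid < annotation$end
      if (any(ov & annotation$class == "exonic")) cls <- "exonic"
      else if (any(ov & annotation$class == "intronic")) cls <- "intronic"
    }
    counts[cls] <- counts[cls] + 1L
  }
  counts
}
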