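# Mini-human-style multiplexed library designer.
#
# Scans a genome for TTTV-PAM protospacers on both strands, applies
# sequence/cloning filters (homopolymer runs, BsmBI sites), counts
# mismatch-tolerant off-targets by annotation class with an exhaustive
# PAM-anchored Hamming scan, ranks candidates per gene and assembles
# multi-guide crRNA arrays.
#
# Coordinates are 0-based half-open on the forward strand; protospacers are
# reported in PAM-strand orientation (the sequence the crRNA spacer matches).

#' Canonical AsCpf1 crRNA direct repeat (19 nt)
#'
#' The scaffold placed before each spacer in a crRNA array. A convention
#' default, not a fixed truth: override wherever a different scaffold is
#' used.
#'
#' @return 19-nt character scalar.
#' @export
default_direct_repeat <- function() "AATTTCTACTCTTGTAGAT"

#' @noRd
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  stopf("genome must be a FASTA path, DNAStringSet, or named character vector")
}

#' Scan a genome for PAM-anchored protospacer candidates
#'
#' Both strands are scanned for the PAM (IUPAC codes allowed; default TTTV,
#' V = A/C/G); every occurrence with at least `protospacer_length` bases 3'
#' of the PAM on its strand yields a candidate. Candidates whose PAM or
#' protospacer contains a non-ACGT base (e.g. N) are dropped.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector of
#'   chromosome sequences.
#' @param pam PAM pattern, 5' of the protospacer (default `"TTTV"`).
#' @param protospacer_length protospacer length (default 20).
#' @return data.frame with `chrom`, `pam_start` (0-based, forward strand),
#'   `strand` (`"+"`/`"-"`), `pam` (the matched 4-mer) and `protospacer`
#'   (PAM-strand orientation).
#' @export
scan_pams <- function(genome, pam = "TTTV", protospacer_length = 20L) {
  genome <- as_genome(genome)
  plen <- as.integer(protospacer_length)
  pam_len <- nchar(pam)
  one_strand <- function(chrom, seqstr, strand) {
    L <- nchar(seqstr)
    if (L < pam_len + plen) return(NULL)
    subject <- Biostrings::DNAString(seqstr)
    hits <- Biostrings::matchPattern(pam, subject, fixed = FALSE)
    s <- Biostrings::start(hits)
    s <- s[s + pam_len - 1L + plen <= L]
    if (!length(s)) return(NULL)
    pam_seq <- substring(seqstr, s, s + pam_len - 1L)
    proto <- substring(seqstr, s + pam_len, s + pam_len + plen - 1L)
    keep <- !grepl("[^ACGT]", pam_seq) & !grepl("[^ACGT]", proto)
    s <- s[keep]; pam_seq <- pam_seq[keep]; proto <- proto[keep]
    if (!length(s)) return(NULL)
    pam_start <- if (strand == "+") s - 1L else L - s - (pam_len - 1L)
    data.frame(chrom = chrom, pam_start = as.integer(pam_start),
               strand = strand, pam = pam_seq, protospacer = proto,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (chrom in names(genome)) {
    seqstr <- genome[[chrom]]
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seqstr)))
    out[[length(out) + 1L]] <- one_strand(chrom, seqstr, "+")
    out[[length(out) + 1L]] <- one_strand(chrom, rc, "-")
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pam_start = integer(),
                      strand = character(), pam = character(),
                      protospacer = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$pam_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply sequence/cloning filters to candidates
#'
#' Homopolymer rule: a T run of `t_run` or more (a Pol III terminator) or
#' any other single-base run of `other_run` or more within the protospacer
#' fails. BsmBI rule: the recognition site CGTCTC or its reverse complement
#' GAGACG anywhere in the protospacer fails (the site is used for array
#' cloning).
#'
#' @param cands candidate data.frame from [scan_pams()].
#' @param t_run minimum failing T-run length (default 4).
#' @param other_run minimum failing A/C/G-run length (default 5).
#' @return `cands` with logical columns `fail_homopolymer`, `fail_bsmbi`
#'   and `pass`.
#' @export
filter_candidates <- function(cands, t_run = 4L, other_run = 5L) {
  homo <- sprintf("T{%d,}|A{%d,}|C{%d,}|G{%d,}",
                  t_run, other_run, other_run, other_run)
  cands$fail_homopolymer <- grepl(homo, cands$protospacer)
  cands$fail_bsmbi <- grepl("CGTCTC|GAGACG", cands$protospacer)
  cands$pass <- !cands$fail_homopolymer & !cands$fail_bsmbi
  cands
}

#' Off-target counting policy
#'
#' `benchmark`: up to one mismatch within the PAM-adjacent 18 nt of the
#' protospacer counts as an off-target hit; candidates with more than
#' `max_offtargets` (2) total hits are excluded. `minihuman`: up to one
#' mismatch anywhere in the 20-mer (the PAM itself must still be a valid
#' PAM site); any exonic or intronic hit excludes the candidate, and
#' survivors are ranked by their intergenic hit count.
#'
#' @param mode `"benchmark"` or `"minihuman"`.
#' @return an `OffTargetPolicy`.
#' @export
offtarget_policy <- function(mode = c("minihuman", "benchmark")) {
  mode <- match.arg(mode)
  if (mode == "benchmark") {
    structure(list(mode = mode, positions = 1:18, max_mismatches = 1L,
                   max_offtargets = 2L), class = "OffTargetPolicy")
  } else {
    structure(list(mode = mode, positions = 1:20, max_mismatches = 1L,
                   max_offtargets = Inf), class = "OffTargetPolicy")
  }
}

#' @noRd
proto_interval <- function(pam_start, strand, pam_len = 4L, plen = 20L) {
  lo <- ifelse(strand == "+", pam_start + pam_len, pam_start - plen)
  cbind(lo = lo, hi = lo + plen)
}

#' @noRd
classify_positions <- function(chrom, mid, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    return(rep("intergenic", length(mid)))
  }
  missing_chrom <- unique(setdiff(chrom, annotation$chrom))
  if (length(missing_chrom)) {
    warnf("chromosome(s) absent from annotation classed intergenic: %s",
          paste(missing_chrom, collapse = ", "))
  }
  vapply(seq_along(mid), function(i) {
    hit <- annotation$chrom == chrom[i] & annotation$start <= mid[i] &
      mid[i] < annotation$end
    if (any(hit & annotation$class == "exonic")) "exonic"
    else if (any(hit & annotation$class == "intronic")) "intronic"
    else "intergenic"
  }, character(1))
}

#' Count mismatch-tolerant off-targets by annotation class
#'
#' Exhaustive PAM-anchored scan: every PAM site in the genome whose
#' protospacer is within the policy's mismatch tolerance of a candidate
#' (over the policy's positions) is a hit; the candidate's own locus is
#' never counted. Hits are classified by the midpoint of their protospacer
#' against the annotation with precedence exonic > intronic > intergenic.
#'
#' @param cands candidate data.frame (rows from [scan_pams()]).
#' @param genome as in [scan_pams()].
#' @param annotation data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `class` (`"exonic"`/`"intronic"`), or `NULL` (all hits
#'   intergenic).
#' @param policy an [offtarget_policy()].
#' @param all_sites optional precomputed [scan_pams()] result for the genome.
#' @return `cands` with integer columns `ot_exonic`, `ot_intronic`,
#'   `ot_intergenic` and `ot_total`.
#' @export
count_offtargets <- function(cands, genome, annotation = NULL,
                             policy = offtarget_policy(), all_sites = NULL) {
  stopifnot(inherits(policy, "OffTargetPolicy"))
  if (is.null(all_sites)) all_sites <- scan_pams(genome)
  if (nrow(all_sites) == 0L || nrow(cands) == 0L) {
    cands$ot_exonic <- cands$ot_intronic <- cands$ot_intergenic <-
      cands$ot_total <- integer(nrow(cands))
    return(cands)
  }
  site_mat <- matrix(unlist(strsplit(all_sites$protospacer, "", fixed = TRUE),
                            use.names = FALSE),
                     nrow = nrow(all_sites), byrow = TRUE)
  site_mat <- site_mat[, policy$positions, drop = FALSE]
  iv <- proto_interval(all_sites$pam_start, all_sites$strand)
  mid <- iv[, "lo"] + 10L
  site_class <- classify_positions(all_sites$chrom, mid, annotation)

  for (cl in c("exonic", "intronic", "intergenic")) {
    cands[[paste0("ot_", cl)]] <- 0L
  }
  for (i in seq_len(nrow(cands))) {
    q <- strsplit(cands$protospacer[i], "", fixed = TRUE)[[1L]][policy$positions]
    mm <- rowSums(site_mat != matrix(q, nrow = nrow(site_mat),
                                     ncol = length(q), byrow = TRUE))
    is_self <- all_sites$chrom == cands$chrom[i] &
      all_sites$pam_start == cands$pam_start[i] &
      all_sites$strand == cands$strand[i]
    hit <- mm <= policy$max_mismatches & !is_self
    for (cl in c("exonic", "intronic", "intergenic")) {
      cands[[paste0("ot_", cl)]][i] <- sum(hit & site_class == cl)
    }
  }
  cands$ot_total <- cands$ot_exonic + cands$ot_intronic + cands$ot_intergenic
  cands
}

#' Rank and select guides for one gene
#'
#' Candidates failing a sequence filter or the policy's off-target exclusion
#' (benchmark: total off-targets above the cap; minihuman: any exonic or
#' intronic off-target) are removed; survivors are ranked lexicographically
#' by (transcripts targeted, descending; intergenic off-targets, ascending;
#' sequence score, descending; distance to first exon, ascending) and the
#' top `k` returned. Missing ranking columns default to neutral values.
#'
#' @param cands candidates for one gene, annotated with filters,
#'   off-target counts and optionally `target_transcripts`,
#'   `sequence_score`, `distance_to_first_exon`.
#' @param k guides to select (default 4).
#' @param policy an [offtarget_policy()].
#' @return the selected rows (possibly fewer than `k`, possibly none).
#' @export
select_guides <- function(cands, k = 4L, policy = offtarget_policy()) {
  stopifnot(inherits(policy, "OffTargetPolicy"))
  if (is.null(cands$target_transcripts)) cands$target_transcripts <- 1L
  if (is.null(cands$sequence_score)) cands$sequence_score <- 0
  if (is.null(cands$distance_to_first_exon)) cands$distance_to_first_exon <- 0L
  keep <- cands$pass
  if (policy$mode == "benchmark") {
    keep <- keep & cands$ot_total <= policy$max_offtargets
  } else {
    keep <- keep & (cands$ot_exonic + cands$ot_intronic) == 0L
  }
  cands <- cands[keep, , drop = FALSE]
  if (nrow(cands) == 0L) return(cands)
  ord <- order(-cands$target_transcripts, cands$ot_intergenic,
               -cands$sequence_score, cands$distance_to_first_exon)
  utils::head(cands[ord, , drop = FALSE], k)
}

#' Assemble a multi-guide crRNA array
#'
#' The array oligo alternates direct repeat and spacer:
#' DR + g1 + DR + g2 + ... (with a 19-nt DR and four guides, 156 nt).
#'
#' @param gene gene name.
#' @param guides character vector of 1-7 20-mer protospacers, in cistron
#'   order.
#' @param direct_repeat crRNA scaffold between guides.
#' @param max_guides synthesis limit (default 7).
#' @return a `GuideArray`: list with `construct_id`, `gene`, `guides`,
#'   `direct_repeat`, `oligo`.
#' @export
build_array <- function(gene, guides, direct_repeat = default_direct_repeat(),
                        max_guides = 7L) {
  if (length(guides) < 1L) stopf("empty guide list")
  if (length(guides) > max_guides) {
    stopf("%d guides exceed the synthesis limit of %d", length(guides), max_guides)
  }
  check_guide_seqs(guides)
  structure(list(construct_id = paste0(gene, "_arr"), gene = gene,
                 guides = guides, direct_repeat = direct_repeat,
                 oligo = paste0(paste0(direct_repeat, guides), collapse = "")),
            class = "GuideArray")
}

#' @export
print.GuideArray <- function(x, ...) {
  cat(sprintf("GuideArray %s (%s): %d guides, %d-nt oligo\n",
              x$construct_id, x$gene, length(x$guides), nchar(x$oligo)))
  invisible(x)
}

#' Combinatorial library size for two-gene perturbation screens
#'
#' Gene-pair space is the ordered-pair count n^2 (self-pairs included). A
#' mono-cistronic pairwise design needs every perturbagen pair, n^2 x p^2
#' vectors; a multiplexed design needs one vector per gene pair, n^2. For
#' 1000 genes and 6 perturbagens per gene: 36,000,000 vs 1,000,000 vectors.
#'
#' @param n_genes number of genes.
#' @param perturbagens_per_gene guides or shRNAs per gene.
#' @param arity genes perturbed per vector; only 2 is supported.
#' @param mode `"mono_pairwise"` or `"multiplexed"`.
#' @return vector count.
#' @export
combinatorial_size <- function(n_genes, perturbagens_per_gene, arity = 2,
                               mode = c("mono_pairwise", "multiplexed")) {
  mode <- match.arg(mode)
  if (arity != 2) stopf("only two-gene combinations (arity = 2) are supported")
  n <- as.numeric(n_genes)
  p <- as.numeric(perturbagens_per_gene)
  switch(mode, mono_pairwise = n^2 * p^2, multiplexed = n^2)
}

#' Genomic span of an array's cut sites
#'
#' Cut sites are approximated as protospacer position `cut_offset` from the
#' PAM (default 18, near the AsCpf1 staggered cut). The span is defined only
#' when all guides sit on one chromosome.
#'
#' @param guides data.frame with `chrom`, `pam_start` (0-based) and `strand`.
#' @param cut_offset protospacer position of the approximate cut (default 18).
#' @return list with `span` (bases, `NA` when undefined) and `defined`.
#' @export
array_span <- function(guides, cut_offset = 18L) {
  stopifnot(all(c("chrom", "pam_start", "strand") %in% names(guides)))
  if (length(unique(guides$chrom)) > 1L) {
    return(list(span = NA_real_, defined = FALSE))
  }
  cut <- ifelse(guides$strand == "+",
                guides$pam_start + 4L + cut_offset,
                guides$pam_start - cut_offset)
  list(span = max(cut) - min(cut), defined = TRUE)
}

#' Design a multiplexed library end to end
#'
#' Scans the genome, filters candidates, assigns them to genes by exon
#' overlap (candidate protospacer midpoint within an exonic interval of the
#' gene), counts off-targets under the policy, scores sequences against an
#' optional preference matrix, selects up to `guides_per_gene` guides per
#' gene and assembles crRNA arrays. Genes ending with fewer than
#' `min_guides` guides go to the dropout manifest instead of the library.
#'
#' @param genome as in [scan_pams()].
#' @param annotation data.frame with `chrom`, `start`, `end`, `class`
#'   (`"exonic"`/`"intronic"`), `gene`, and optionally `transcript_count`
#'   and `first_exon_start`.
#' @param score_table optional `ScoreTable` for sequence scoring.
#' @param guides_per_gene target guides per array (default 4).
#' @param min_guides minimum guides for a gene to enter the library
#'   (default 3, as in a 4-guide library that tolerates 3-guide arrays).
#' @param policy an [offtarget_policy()].
#' @param direct_repeat crRNA scaffold.
#' @return list with `library` (`GuideLibrary`, mode `cpf1_multi`), `arrays`
#'   (list of `GuideArray`), `candidates` (annotated data.frame) and
#'   `dropouts` (genes with too few surviving guides).
#' @export
design_library <- function(genome, annotation, score_table = NULL,
                           guides_per_gene = 4L, min_guides = 3L,
                           policy = offtarget_policy("minihuman"),
                           direct_repeat = default_direct_repeat()) {
  stopifnot(is.data.frame(annotation),
            all(c("chrom", "start", "end", "class", "gene") %in% names(annotation)))
  all_sites <- scan_pams(genome)
  cands <- filter_candidates(all_sites)
  iv <- proto_interval(cands$pam_start, cands$strand)
  cands$proto_mid <- iv[, "lo"] + 10L

  exons <- annotation[annotation$class == "exonic", , drop = FALSE]
  assigned <- do.call(rbind, lapply(seq_len(nrow(cands)), function(i) {
    hit <- exons$chrom == cands$chrom[i] & exons$start <= cands$proto_mid[i] &
      cands$proto_mid[i] < exons$end
    if (!any(hit)) return(NULL)
    genes <- unique(exons$gene[hit])
    do.call(rbind, lapply(genes, function(gn) {
      rows <- exons[hit & exons$gene == gn, , drop = FALSE]
      out <- cands[i, , drop = FALSE]
      out$gene <- gn
      out$target_transcripts <- if ("transcript_count" %in% names(rows)) {
        max(rows$transcript_count)
      } else 1L
      fes <- if ("first_exon_start" %in% names(rows)) rows$first_exon_start[1L] else NA
      out$distance_to_first_exon <- if (is.na(fes)) 0L else
        abs(out$proto_mid - as.integer(fes))
      out
    }))
  }))
  if (is.null(assigned) || nrow(assigned) == 0L) {
    stopf("no candidate overlaps any exonic interval")
  }
  assigned <- count_offtargets(assigned, genome, annotation, policy,
                               all_sites = all_sites)
  assigned$sequence_score <- if (!is.null(score_table)) {
    score_guides(assigned$protospacer, score_table)$score
  } else 0

  arrays <- list()
  dropouts <- character()
  lib_rows <- list()
  for (gn in unique(annotation$gene)) {
    sel <- select_guides(assigned[assigned$gene == gn, , drop = FALSE],
                         k = guides_per_gene, policy = policy)
    if (nrow(sel) < min_guides) {
      dropouts <- c(dropouts, gn)
      next
    }
    arr <- build_array(gn, sel$protospacer, direct_repeat)
    arrays[[gn]] <- arr
    lib_rows[[gn]] <- data.frame(construct_id = arr$construct_id, gene = gn,
                                 cistron = seq_along(arr$guides),
                                 sequence = arr$guides,
                                 stringsAsFactors = FALSE)
  }
  if (!length(lib_rows)) stopf("every gene dropped out of the design")
  list(library = guide_library(do.call(rbind, lib_rows), "cpf1_multi"),
       arrays = arrays, candidates = assigned, dropouts = dropouts)
}
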