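# Domain types and TSV I/O for guide libraries, read counts and reference
# gene sets.
#
# A GuideLibrary holds constructs; each construct targets one gene with an
# ordered list of 20-nt protospacers (one guide for mono-cistronic Cas9 or
# AsCpf1 libraries, 1-7 guides on a single crRNA array for multiplexed
# AsCpf1 libraries). Non-targeting control constructs carry the sentinel
# gene label "NonTargeting".

#' Sentinel gene label for non-targeting control constructs
#'
#' Constructs labelled with this gene are kept in construct-level output but
#' excluded from all gene-level statistics.
#'
#' @export
NON_TARGETING <- "NonTargeting"

#' Supported nuclease/library modes
#' @noRd
NUCLEASE_MODES <- c("cas9_mono", "cpf1_mono", "cpf1_multi")

#' Construct a guide library
#'
#' @param guides data.frame with columns `construct_id`, `gene`, `cistron`
#'   (1-based position of the guide within its construct) and `sequence`
#'   (20-nt protospacer, ACGT).
#' @param mode one of `"cas9_mono"`, `"cpf1_mono"` (one guide per construct)
#'   or `"cpf1_multi"` (1-7 guides per construct).
#'
#' @return A `GuideLibrary` object.
#' @export
guide_library <- function(guides, mode) {
  mode <- match.arg(mode, NUCLEASE_MODES)
  stopifnot(is.data.frame(guides),
            all(c("construct_id", "gene", "cistron", "sequence") %in%
                  names(guides)))
  guides <- guides[, c("construct_id", "gene", "cistron", "sequence")]
  guides$construct_id <- as.character(guides$construct_id)
  guides$gene <- as.character(guides$gene)
  guides$cistron <- as.integer(guides$cistron)
  guides$sequence <- toupper(as.character(guides$sequence))
  lib <- structure(list(guides = guides, mode = mode), class = "GuideLibrary")
  validate_guide_library(lib)
  lib
}

#' @noRd
validate_guide_library <- function(lib) {
  g <- lib$guides
  if (nrow(g) > 0L) {
    if (any(g$gene == "" | is.na(g$gene))) stopf("gene label must be non-empty")
    check_guide_seqs(g$sequence)
    dup <- duplicated(paste(g$construct_id, g$cistron))
    if (any(dup)) {
      stopf("duplicate (construct_id, cistron): %s",
            paste(g$construct_id[dup][1L], g$cistron[dup][1L]))
    }
    # one gene per construct
    per <- tapply(g$gene, g$construct_id, function(x) length(unique(x)))
    if (any(per > 1L)) {
      stopf("construct '%s' maps to more than one gene",
            names(per)[per > 1L][1L])
    }
    n_guides <- table(g$construct_id)
    if (lib$mode %in% c("cas9_mono", "cpf1_mono") && any(n_guides != 1L)) {
      stopf("mode '%s' requires exactly 1 guide per construct ('%s' has %d)",
            lib$mode, names(n_guides)[n_guides != 1L][1L],
            n_guides[n_guides != 1L][1L])
    }
    if (lib$mode == "cpf1_multi" && any(n_guides > 7L)) {
      stopf("cpf1_multi allows at most 7 guides per construct ('%s' has %d)",
            names(n_guides)[n_guides > 7L][1L], max(n_guides))
    }
  }
  invisible(lib)
}

#' Construct identifiers of a library, in input order
#' @param lib a `GuideLibrary`.
#' @return character vector of construct ids.
#' @export
construct_ids <- function(lib) {
  unique(lib$guides$construct_id)
}

#' Construct-to-gene map of a library
#' @param lib a `GuideLibrary`.
#' @return named character vector, names are construct ids.
#' @export
construct_genes <- function(lib) {
  g <- lib$guides[!duplicated(lib$guides$construct_id), ]
  stats::setNames(g$gene, g$construct_id)
}

#' @export
print.GuideLibrary <- function(x, ...) {
  s <- summarize_library(x)
  cat(sprintf("GuideLibrary (%s): %d constructs, %d guides, %d genes, %d non-targeting\n",
              x$mode, s$n_constructs, s$n_guides, s$n_genes, s$n_nontargeting))
  invisible(x)
}

#' Read a guide library from TSV
#'
#' The expected dialect is tab-separated, UTF-8, one mandatory header row
#' `construct_id  gene  guide_1 ... guide_k` (k <= 7); lines starting with
#' `#` are skipped. Ragged multiplexed arrays (e.g. 3-guide constructs in a
#' 4-guide library) leave trailing guide cells empty.
#'
#' @param path TSV file path.
#' @param mode nuclease/library mode, see [guide_library()].
#' @return A `GuideLibrary`.
#' @export
read_library <- function(path, mode) {
  mode <- match.arg(mode, NUCLEASE_MODES)
  x <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "#", colClasses = "character",
                         check.names = FALSE)
  if (!all(c("construct_id", "gene") %in% names(x))) {
    stopf("library TSV must have 'construct_id' and 'gene' columns")
  }
  gcols <- grep("^guide_[0-9]+$", names(x), value = TRUE)
  if (length(gcols) == 0L) stopf("library TSV has no guide_<k> columns")
  if (length(gcols) > 7L) stopf("at most 7 guide columns supported")
  gcols <- gcols[order(as.integer(sub("^guide_", "", gcols)))]

  dup <- duplicated(x$construct_id)
  if (any(dup)) stopf("duplicate construct_id '%s'", x$construct_id[dup][1L])

  rows <- list()
  for (j in seq_along(gcols)) {
    seqs <- toupper(trimws(x[[gcols[j]]]))
    keep <- !is.na(seqs) & seqs != ""
    if (!any(keep)) next
    bad <- keep & grepl("[^ACGT]", seqs)
    if (any(bad)) {
      stopf("non-ACGT character in column %s, row %d", gcols[j], which(bad)[1L])
    }
    bad <- keep & nchar(seqs) != 20L
    if (any(bad)) {
      stopf("guide length != 20 in column %s, row %d", gcols[j], which(bad)[1L])
    }
    rows[[j]] <- data.frame(construct_id = x$construct_id[keep],
                            gene = x$gene[keep],
                            cistron = j,
                            sequence = seqs[keep],
                            stringsAsFactors = FALSE)
  }
  guides <- do.call(rbind, rows)
  if (is.null(guides)) {
    guides <- data.frame(construct_id = character(), gene = character(),
                         cistron = integer(), sequence = character(),
                         stringsAsFactors = FALSE)
  } else {
    # restore construct (input) order, cistron within construct
    guides <- guides[order(match(guides$construct_id, x$construct_id),
                           guides$cistron), , drop = FALSE]
    rownames(guides) <- NULL
    # cistrons must be gap-free so guide order within the array is preserved
    gaps <- tapply(guides$cistron, guides$construct_id,
                   function(k) !identical(sort(k), seq_along(k)))
    if (any(gaps)) {
      stopf("construct '%s' has a gap in its guide columns (only trailing cells may be empty)",
            names(gaps)[gaps][1L])
    }
  }
  guide_library(guides, mode)
}

#' Write a guide library as canonical TSV
#'
#' Inverse of [read_library()]: `write_library(read_library(x))` reproduces a
#' canonical input file byte for byte.
#'
#' @param lib a `GuideLibrary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  ids <- construct_ids(lib)
  k <- if (nrow(lib$guides)) max(lib$guides$cistron) else 1L
  wide <- matrix("", nrow = length(ids), ncol = k,
                 dimnames = list(ids, paste0("guide_", seq_len(k))))
  if (nrow(lib$guides)) {
    wide[cbind(match(lib$guides$construct_id, ids), lib$guides$cistron)] <-
      lib$guides$sequence
  }
  genes <- construct_genes(lib)[ids]
  header <- paste(c("construct_id", "gene", colnames(wide)), collapse = "\t")
  body <- if (length(ids)) {
    paste(ids, genes, apply(wide, 1L, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, body), path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Summarize a guide library
#'
#' @param lib a `GuideLibrary`.
#' @return list with `n_constructs`, `n_guides`, `n_genes` (excluding the
#'   non-targeting sentinel), `n_nontargeting` (constructs), and
#'   `guides_per_construct` (a named table, e.g. how many 3- and 4-guide
#'   arrays the library holds).
#' @export
summarize_library <- function(lib) {
  g <- lib$guides
  ids <- construct_ids(lib)
  genes <- construct_genes(lib)
  per <- if (length(ids)) table(factor(g$construct_id, levels = ids)) else table(integer())
  hist <- table(as.integer(per))
  structure(list(
    n_constructs = length(ids),
    n_guides = nrow(g),
    n_genes = length(unique(genes[genes != NON_TARGETING])),
    n_nontargeting = sum(genes == NON_TARGETING),
    guides_per_construct = hist
  ), class = "LibrarySummary")
}

#' @export
print.LibrarySummary <- function(x, ...) {
  cat(sprintf("constructs: %d | guides: %d | genes: %d | non-targeting: %d\n",
              x$n_constructs, x$n_guides, x$n_genes, x$n_nontargeting))
  if (length(x$guides_per_construct)) {
    cat("guides/construct:",
        paste(sprintf("%sx%s", x$guides_per_construct,
                      names(x$guides_per_construct)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Concatenate guide libraries
#' @param lib,... `GuideLibrary` objects of the same mode.
#' @return a `GuideLibrary`.
#' @export
concat_libraries <- function(lib, ...) {
  rest <- list(...)
  modes <- vapply(c(list(lib), rest), `[[`, "", "mode")
  if (length(unique(modes)) != 1L) stopf("libraries have different modes")
  guide_library(do.call(rbind, lapply(c(list(lib), rest), `[[`, "guides")),
                lib$mode)
}

# ---- reference gene sets ----------------------------------------------------

#' Read a one-gene-per-line gene set
#' @param path text file, one gene per line; blank lines and `#` comments skipped.
#' @return character vector.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[x != "" & !startsWith(x, "#")]
}

#' Gold-standard reference gene sets
#'
#' Essential and non-essential gene sets used as positives and negatives in
#' benchmarking (the benchmark libraries target 342 core-essential and 345
#' non-essential genes).
#'
#' @param essential,non_essential character vectors of gene names; must be
#'   non-empty and disjoint.
#' @return a `ReferenceSets` object.
#' @export
reference_sets <- function(essential, non_essential) {
  essential <- unique(as.character(essential))
  non_essential <- unique(as.character(non_essential))
  if (length(essential) == 0L || length(non_essential) == 0L) {
    stopf("both reference sets must be non-empty")
  }
  ov <- intersect(essential, non_essential)
  if (length(ov)) stopf("reference sets overlap (e.g. '%s')", ov[1L])
  structure(list(essential = essential, non_essential = non_essential),
            class = "ReferenceSets")
}

#' @export
print.ReferenceSets <- function(x, ...) {
  cat(sprintf("ReferenceSets: %d essential, %d non-essential\n",
              length(x$essential), length(x$non_essential)))
  invisible(x)
}

# ---- count matrices ---------------------------------------------------------

#' Parse screen sample labels
#'
#' Labels follow `T<k>_R<j>` for timepoint k of replicate j and
#' `T0_ref_R<j>` for the reference (pre-screen) sample of replicate j.
#'
#' @param labels character vector.
#' @return data.frame with `label`, `timepoint`, `replicate`, `is_reference`.
#' @export
parse_sample_labels <- function(labels) {
  ref <- grepl("^T0_ref_R[0-9]+$", labels)
  tp <- grepl("^T[0-9]+_R[0-9]+$", labels)
  bad <- !(ref | tp)
  if (any(bad)) stopf("unparseable sample label '%s'", labels[bad][1L])
  timepoint <- rep(0L, length(labels))
  timepoint[tp] <- as.integer(sub("^T([0-9]+)_R[0-9]+$", "\\1", labels[tp]))
  data.frame(
    label = labels,
    timepoint = timepoint,
    replicate = as.integer(sub("^.*_R([0-9]+)$", "\\1", labels)),
    is_reference = ref,
    stringsAsFactors = FALSE
  )
}

#' Construct a count matrix
#'
#' @param counts integer matrix, constructs x samples; rownames are construct
#'   ids, colnames are sample labels (see [parse_sample_labels()]).
#' @param samples optional pre-parsed sample table.
#' @return a `CountMatrix`.
#' @export
count_matrix <- function(counts, samples = parse_sample_labels(colnames(counts))) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stopf("negative count")
  if (any(counts != floor(counts))) stopf("non-integer count")
  storage.mode(counts) <- "integer"
  # exactly one reference sample per replicate
  for (r in unique(samples$replicate)) {
    n_ref <- sum(samples$is_reference & samples$replicate == r)
    if (n_ref != 1L) {
      stopf("replicate %d has %d reference samples (exactly 1 required)", r, n_ref)
    }
  }
  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d constructs x %d samples (%d replicates, timepoints %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$replicate)),
              paste(sort(unique(x$samples$timepoint[!x$samples$is_reference])),
                    collapse = ",")))
  invisible(x)
}

#' Read a read-count matrix from TSV
#'
#' First column `construct_id`, remaining columns sample labels. Constructs
#' are aligned to the library order; constructs present in the library but
#' absent from the file are reported with a warning; a construct absent from
#' the library is a hard error.
#'
#' @param path TSV file path.
#' @param library the `GuideLibrary` the counts belong to.
#' @return a `CountMatrix`.
#' @export
read_counts <- function(path, library) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "#", check.names = FALSE)
  if (names(x)[1L] != "construct_id") {
    stopf("first column of a counts TSV must be 'construct_id'")
  }
  ids <- construct_ids(library)
  extra <- setdiff(x$construct_id, ids)
  if (length(extra)) stopf("construct '%s' in counts is absent from library", extra[1L])
  missing <- setdiff(ids, x$construct_id)
  if (length(missing)) {
    warnf("%d library constructs missing from counts (e.g. %s)",
          length(missing), missing[1L])
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (any(is.na(m))) stopf("missing count value")
  if (any(m < 0)) stopf("negative count")
  rownames(m) <- x$construct_id
  m <- m[match(intersect(ids, x$construct_id), rownames(m)), , drop = FALSE]
  zero_cols <- colnames(m)[colSums(m) == 0]
  if (length(zero_cols)) {
    warnf("all-zero count column(s): %s", paste(zero_cols, collapse = ", "))
  }
  storage.mode(m) <- "integer"
  count_matrix(m)
}

#' Write a count matrix as TSV
#' @param cm a `CountMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(construct_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
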