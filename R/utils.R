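# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Valid protospacer alphabet; guides are stored uppercase.
#' @noRd
check_guide_seqs <- function(seqs, where = "guide") {
  bad_len <- nchar(seqs) != 20L
  if (any(bad_len)) {
    stopf("%s length must be 20 nt (violations at entries: %s)", where,
          paste(utils::head(which(bad_len), 5L), collapse = ", "))
  }
  bad_chr <- grepl("[^ACGT]", seqs)
  if (any(bad_chr)) {
    stopf("%s contains non-ACGT character (entries: %s)", where,
          paste(utils::head(which(bad_chr), 5L), collapse = ", "))
  }
  invisible(TRUE)
}
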