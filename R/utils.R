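#' @keywords internal
"_PACKAGE"

TRANSCRIPT_CLASSES <- c("mRNA", "lncRNA", "circRNA", "miRNA")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions so callers (and tests) can distinguish malformed input
## files from bad configuration.
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("olfcerna_format_error", "olfcerna_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("olfcerna_config_error", "olfcerna_error")))
}

stop_dependency <- function(...) {
  stop(errorCondition(paste0(...), class = c("olfcerna_dependency_error", "olfcerna_error")))
}

#' Evaluate an expression under a fixed, platform-stable RNG state
#'
#' Pins the generator kinds (Mersenne-Twister / Inversion / Rejection) so a
#' seed reproduces bit-identically across platforms and R sessions, and
#' restores the caller's RNG state afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

## Atomic file write: render to a sibling temp file, then rename, so an
## interrupted run never leaves a truncated output.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file onto ", path)
  }
  invisible(path)
}

## Full-precision numeric formatting for TSV round-trips.
format_full <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%d", as.integer(x)),
         sprintf("%.17g", x))
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and maps T to U; errors on any character outside ACGU.
#'
#' @param x character vector of sequences.
#' @param id optional identifiers used in error messages.
#' @return character vector over ACGU.
#' @export
normalize_rna <- function(x, id = NULL) {
  y <- chartr("acgut", "ACGUU", toupper(x))
  y <- chartr("T", "U", y)
  bad <- grepl("[^ACGU]", y)
  if (any(bad)) {
    which_id <- if (!is.null(id)) id[bad][1] else which(bad)[1]
    stop_format("sequence ", which_id, " contains characters outside the ACGU/ACGT alphabet")
  }
  y
}

#' Reverse complement of an RNA sequence
#'
#' Antiparallel complement (A<->U, C<->G), returned 5'->3'.
#'
#' @param x character vector of RNA sequences (ACGU).
#' @return character vector of reverse complements.
#' @export
reverse_complement_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}
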