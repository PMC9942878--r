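# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' IUPAC nucleotide classes
#'
#' Mapping from IUPAC ambiguity codes to the set of concrete bases each
#' admits. `N` in a *genome* matches nothing (it is an unknown base), so the
#' class tables here describe the rule side only; genome-side handling is in
#' the matching functions.
#' @noRd
.iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (!is.character(x) || length(x) != 1L || nchar(x) < 1L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  x <- toupper(x)
  if (grepl(sprintf("[^%s]", alphabet), x))
    stop(what, " contains characters outside {", alphabet, "}", call. = FALSE)
  x
}

.check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single number in [0, 1]", call. = FALSE)
  x
}

.check_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(what, " must be an integer >= ", min, call. = FALSE)
  as.integer(x)
}

#' Reverse-complement a plain character DNA string
#' @noRd
.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Derive a deterministic substream seed from a master seed and a label
#'
#' Generators draw from independent substreams keyed by stable labels, so
#' adding one simulation stage never perturbs the draws of another. The
#' derivation is a small multiply-accumulate hash of the label folded into
#' the master seed, kept inside the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed master integer seed.
#' @param label a stable character label for the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  seed <- .check_count(seed, "seed")
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((seed * 2654435 + h) %% 2147483647)
}

# Evaluate `expr` under a substream seed, restoring the caller's RNG state.
.with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  expr
}
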