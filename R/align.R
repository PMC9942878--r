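#' Default alignment scoring
#'
#' Affine-gap global alignment parameters: match +2, mismatch -4, gap open
#' 10 and gap extension 1 (both penalties positive, subtracted once per gap
#' and per gapped base). The heavy gap-open cost keeps a single 6-10 bp
#' repair deletion as one gap instead of splitting it; `max_edit_frac` is
#' the unalignable-read ceiling (mismatch plus gap columns as a fraction of
#' the reference length).
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext affine gap penalties (positive).
#' @param max_edit_frac reads whose alignment has more than
#'   `max_edit_frac * nchar(ref)` edited columns are flagged unalignable.
#' @return a list of scoring parameters.
#' @export
align_params <- function(match = 2, mismatch = -4, gap_open = 10, gap_ext = 1,
                         max_edit_frac = 0.25) {
  stopifnot(gap_open >= 0, gap_ext >= 0, max_edit_frac > 0, max_edit_frac <= 1)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, max_edit_frac = max_edit_frac)
}

# Vectorized global alignment of many reads against one reference.
# Returns a list of gapped (pattern, subject) string pairs plus scores.
.align_strings <- function(reads, refseq, params) {
  .align_pair_cpp(reads, refseq, params$match, params$mismatch,
                  params$gap_open, params$gap_ext)
}

#' Globally align one amplicon read to its reference
#'
#' End-to-end (global) alignment under affine-gap scoring. Reads shorter
#' than half the reference, or whose optimal alignment contains more edited
#' columns than the configured ceiling, are flagged unalignable; the
#' quantification pipeline excludes such reads from both numerator and
#' denominator.
#'
#' @param read read sequence (character, A/C/G/T/N).
#' @param ref reference as a character string or [amplicon_ref()].
#' @param params scoring from [align_params()].
#' @return an object of class `amplicon_alignment`: gapped `pattern` (read)
#'   and `subject` (reference) strings, `score`, `n_edit_cols`, and
#'   `aligned` (FALSE when flagged unalignable).
#' @export
align_read <- function(read, ref, params = align_params()) {
  read <- .check_dna(read, "read", allow_n = TRUE)
  if (inherits(ref, "amplicon_ref")) ref <- ref$sequence
  ref <- .check_dna(ref, "ref", allow_n = TRUE)
  if (nchar(read) < nchar(ref) / 2) {
    return(structure(list(read = read, ref = ref, pattern = NA_character_,
                          subject = NA_character_, score = NA_real_,
                          n_edit_cols = NA_integer_, aligned = FALSE),
                     class = "amplicon_alignment"))
  }
  a <- .align_strings(read, ref, params)
  res <- structure(list(read = read, ref = ref, pattern = a$pattern,
                        subject = a$subject, score = a$score,
                        n_edit_cols = .count_edit_cols(a$pattern, a$subject),
                        aligned = TRUE),
                   class = "amplicon_alignment")
  if (res$n_edit_cols > params$max_edit_frac * nchar(ref)) res$aligned <- FALSE
  res
}

.count_edit_cols <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  sum(p == "-" | s == "-" | p != s)
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  if (!x$aligned) {
    cat("unalignable read (", nchar(x$read), " nt)\n", sep = "")
  } else {
    cat(sprintf("global alignment, score %.0f, %d edited column(s)\n",
                x$score, x$n_edit_cols))
  }
  invisible(x)
}
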