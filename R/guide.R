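#' Guide specification
#'
#' Describes one guide RNA: its spacer sequence, the 5' PAM rule the
#' nuclease requires next to the protospacer, and the protospacer's
#' coordinates on the reference (0-based, half-open). The default PAM rule
#' `"TBN"` (B = G, T or C) is the minimal T-rich motif of the hypercompact
#' CasPhi-2 nuclease; spacers are typically 20 bp (30 bp supported).
#'
#' @param name identifier for the guide.
#' @param spacer spacer sequence (DNA, A/C/G/T).
#' @param pam_rule IUPAC string matched immediately 5' of the protospacer.
#' @param target_chrom,target_start,target_end,target_strand protospacer
#'   coordinates on the reference; `target_end - target_start` must equal
#'   the spacer length. Coordinates are 0-based half-open.
#' @return an object of class `guide_spec`.
#' @examples
#' guide_spec("g10", spacer = paste(rep("ACGT", 5), collapse = ""),
#'            target_chrom = "amp", target_start = 100, target_end = 120)
#' @export
guide_spec <- function(name, spacer, pam_rule = "TBN",
                       target_chrom = NA_character_, target_start = NA_integer_,
                       target_end = NA_integer_, target_strand = "+") {
  spacer <- .check_dna(spacer, "spacer")
  pam_rule <- toupper(pam_rule)
  if (!all(strsplit(pam_rule, "")[[1]] %in% names(.iupac)))
    stop("pam_rule must be an IUPAC string", call. = FALSE)
  if (!is.na(target_start) && !is.na(target_end) &&
      (target_end - target_start) != nchar(spacer))
    stop("target_end - target_start must equal the spacer length", call. = FALSE)
  if (!target_strand %in% c("+", "-"))
    stop("target_strand must be '+' or '-'", call. = FALSE)
  structure(list(
    name = as.character(name), spacer = spacer, pam_rule = pam_rule,
    target_chrom = as.character(target_chrom),
    target_start = as.integer(target_start), target_end = as.integer(target_end),
    target_strand = target_strand
  ), class = "guide_spec")
}

#' @export
print.guide_spec <- function(x, ...) {
  cat(sprintf("guide '%s': 5'-%s-3' PAM + %d nt spacer %s\n", x$name,
              x$pam_rule, nchar(x$spacer), x$spacer))
  if (!is.na(x$target_start))
    cat(sprintf("  target %s:%d-%d (%s)\n", x$target_chrom, x$target_start,
                x$target_end, x$target_strand))
  invisible(x)
}

#' Amplicon reference
#'
#' A reference amplicon sequence together with the guide that targets it and
#' the homopolymer mask intervals used during edited-read classification.
#' Long single-base runs (notoriously, adenine stretches near some targets)
#' are error-prone during PCR, so indels confined to them are not trusted as
#' edits; masks are detected with [detect_homopolymer_masks()] unless given.
#'
#' @param id reference identifier.
#' @param sequence amplicon sequence (A/C/G/T/N).
#' @param guide a [guide_spec()] whose target lies inside this amplicon.
#' @param mask_intervals optional 2-column matrix of 0-based half-open
#'   intervals to mask; computed from `min_homopolymer_run` when `NULL`.
#' @param min_homopolymer_run minimum run length that triggers a mask.
#' @return an object of class `amplicon_ref`.
#' @export
amplicon_ref <- function(id, sequence, guide, mask_intervals = NULL,
                         min_homopolymer_run = 8L) {
  sequence <- .check_dna(sequence, "sequence", allow_n = TRUE)
  stopifnot(inherits(guide, "guide_spec"))
  if (!is.na(guide$target_start) &&
      (guide$target_start < 0 || guide$target_end > nchar(sequence)))
    stop("guide target lies outside the amplicon", call. = FALSE)
  if (is.null(mask_intervals))
    mask_intervals <- detect_homopolymer_masks(sequence, min_homopolymer_run)
  mask_intervals <- .check_intervals(mask_intervals, nchar(sequence))
  structure(list(id = as.character(id), sequence = sequence, guide = guide,
                 mask_intervals = mask_intervals),
            class = "amplicon_ref")
}

.check_intervals <- function(iv, seqlen) {
  iv <- as.matrix(iv)
  if (length(iv) == 0L) return(matrix(integer(), ncol = 2L,
                                      dimnames = list(NULL, c("start", "end"))))
  if (ncol(iv) != 2L) stop("mask_intervals must have two columns", call. = FALSE)
  colnames(iv) <- c("start", "end")
  storage.mode(iv) <- "integer"
  if (any(iv[, 1] < 0L) || any(iv[, 2] > seqlen) || any(iv[, 1] >= iv[, 2]))
    stop("mask intervals out of bounds or empty", call. = FALSE)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2]))
    stop("mask intervals overlap", call. = FALSE)
  iv
}

#' Test a PAM triplet against an IUPAC rule
#'
#' Returns `TRUE` when every base of `triplet` belongs to the IUPAC class at
#' the matching position of `rule`. An `N` in the *observed* sequence is an
#' unknown base: it fails every class except the rule's own `N`.
#'
#' @param triplet observed PAM-length sequence (genome side).
#' @param rule IUPAC rule string (e.g. `"TBN"`), same length as `triplet`.
#' @return logical scalar.
#' @examples
#' pam_match("TGA", "TBN")  # TRUE:  B admits G
#' pam_match("TAA", "TBN")  # FALSE: B excludes A
#' @export
pam_match <- function(triplet, rule) {
  triplet <- toupper(triplet); rule <- toupper(rule)
  if (nchar(triplet) != nchar(rule))
    stop("PAM sequence and rule differ in length", call. = FALSE)
  tb <- strsplit(triplet, "")[[1]]
  rb <- strsplit(rule, "")[[1]]
  if (!all(rb %in% names(.iupac))) stop("invalid IUPAC code in rule", call. = FALSE)
  for (i in seq_along(rb)) {
    if (tb[i] == "N") {
      if (rb[i] != "N") return(FALSE)
    } else if (!tb[i] %in% .iupac[[rb[i]]]) return(FALSE)
  }
  TRUE
}
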