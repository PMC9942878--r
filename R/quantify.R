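#' Quantify editing from amplicon reads
#'
#' End-to-end quantification: reads are deduplicated to unique sequences,
#' aligned globally to the reference, indel events are extracted and
#' left-normalized, patterns are aggregated and the edited-read
#' classification applied. Reads failing alignment (too short, or beyond
#' the edit ceiling) are excluded from both the numerator and the
#' denominator and reported in `n_unaligned`.
#'
#' Unique read sequences identical in length to the reference and carrying
#' only a handful of substitutions take a fast path that skips the dynamic
#' program: with affine gap costs (open 10) a compensating
#' insertion-deletion pair can only beat plain mismatches when it repairs
#' four or more of them, which cannot happen by chance at the mismatch
#' counts admitted here.
#'
#' @param reads character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param ref an [amplicon_ref()].
#' @param cfg an [edit_call_config()].
#' @param params alignment scoring from [align_params()].
#' @return list of class `quant_result`: `result` (the [classify_edited()]
#'   `edit_result`), `pattern_table`, `n_input`, `n_unaligned`,
#'   `size_profile`.
#' @export
quantify_editing <- function(reads, ref, cfg = edit_call_config(),
                             params = align_params()) {
  stopifnot(inherits(ref, "amplicon_ref"))
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  refseq <- ref$sequence
  reflen <- nchar(refseq)
  refchars <- strsplit(refseq, "")[[1]]

  tab <- table(reads)
  useq <- names(tab)
  w <- as.integer(tab)

  too_short <- nchar(useq) < reflen / 2
  events <- vector("list", length(useq))
  aligned <- !too_short
  ceiling_cols <- params$max_edit_frac * reflen

  # fast path: same-length, few substitutions, no indel possible
  same_len <- !too_short & nchar(useq) == reflen
  mism <- rep(NA_integer_, length(useq))
  if (any(same_len)) {
    idx <- which(same_len)
    mat <- as.matrix(Biostrings::DNAStringSet(useq[idx]))
    refmat <- matrix(refchars, nrow = length(idx), ncol = reflen, byrow = TRUE)
    mism[idx] <- as.integer(rowSums(mat != refmat))
  }
  fast <- same_len & !is.na(mism) & mism <= 8L
  for (i in which(fast)) events[[i]] <- .empty_events()

  # full alignment for the rest
  todo <- which(!too_short & !fast)
  if (length(todo)) {
    a <- .align_strings(useq[todo], refseq, params)
    for (k in seq_along(todo)) {
      i <- todo[k]
      necols <- .count_edit_cols(a$pattern[k], a$subject[k])
      if (necols > ceiling_cols) {
        aligned[i] <- FALSE
        next
      }
      events[[i]] <- extract_indels(
        list(pattern = a$pattern[k], subject = a$subject[k]), refseq)
    }
  }

  n_unaligned <- sum(w[!aligned])
  keep <- which(aligned)
  pt <- build_pattern_table(events[keep], n_total = sum(w[keep]),
                            weights = w[keep])
  res <- classify_edited(pt, cfg, ref$mask_intervals)
  structure(list(result = res, pattern_table = pt,
                 n_input = sum(w), n_unaligned = n_unaligned,
                 size_profile = deletion_size_profile(res)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("%s input reads, %s unalignable (excluded)\n",
              format(x$n_input, big.mark = ","),
              format(x$n_unaligned, big.mark = ",")))
  print(x$result)
  invisible(x)
}

#' Export a pattern table as a flat data.frame
#'
#' One row per pattern with its classification outcome, suitable for
#' writing to TSV.
#'
#' @param quant a `quant_result` from [quantify_editing()].
#' @return data.frame with pattern key, kind, size, start, count,
#'   `qualifies`, and `exclusion_reason`.
#' @export
pattern_report <- function(quant) {
  stopifnot(inherits(quant, "quant_result"))
  q <- quant$result$qualifying_patterns
  e <- quant$result$excluded_patterns
  if (nrow(q)) { q$qualifies <- TRUE; q$exclusion_reason <- "" }
  else { q$qualifies <- logical(); q$exclusion_reason <- character() }
  if (nrow(e)) { e$qualifies <- FALSE; e$exclusion_reason <- e$reason }
  else { e$qualifies <- logical(); e$exclusion_reason <- character() }
  e$reason <- NULL
  out <- rbind(q, e)
  out <- out[order(-out$count, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
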