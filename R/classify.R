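#' Edited-read classification thresholds
#'
#' The thresholds separating true edits from PCR/sequencing artifacts:
#' control samples show 1 bp (occasionally 2 bp) indel patterns with >100
#' supporting reads, and larger indels only at very low read counts, so a
#' pattern is trusted as an edit only when its indel is at least
#' `min_indel_size` (default 3 bp) *and* it is supported by at least
#' `min_pattern_reads` reads (default 100 at typical 1-5 million read
#' depth; 10 is the documented adjustment for shallow runs under ~1e5
#' reads). Indels confined to homopolymer runs of `min_homopolymer_run` or
#' longer are additionally excluded.
#'
#' @param min_indel_size minimum indel size in bp (default 3).
#' @param min_pattern_reads minimum supporting reads per pattern
#'   (default 100; use 10 for shallow runs).
#' @param min_homopolymer_run run length at which masking starts (default 8).
#' @return a list of class `edit_call_config`.
#' @export
edit_call_config <- function(min_indel_size = 3L, min_pattern_reads = 100L,
                             min_homopolymer_run = 8L) {
  structure(list(
    min_indel_size = .check_count(min_indel_size, "min_indel_size", 1L),
    min_pattern_reads = .check_count(min_pattern_reads, "min_pattern_reads", 1L),
    min_homopolymer_run = .check_count(min_homopolymer_run,
                                       "min_homopolymer_run", 2L)),
    class = "edit_call_config")
}

# An event (with its ambiguity range) is masked iff the whole range
# [start, ambiguity_end + size) for deletions, or the touched positions
# [start, ambiguity_end) boundary set for insertions, sits inside ONE mask
# interval. Partial overlap does not mask.
.pattern_masked <- function(kind, start, size, ambiguity_end, masks) {
  if (is.null(masks) || nrow(masks) == 0L) return(FALSE)
  lo <- start
  hi <- if (kind == "deletion") ambiguity_end + size else ambiguity_end
  any(masks[, 1] <= lo & hi <= masks[, 2])
}

#' Classify edited reads from a pattern table
#'
#' Applies the edited-read criterion: a pattern qualifies iff its indel size
#' is at least `cfg$min_indel_size`, its read count at least
#' `cfg$min_pattern_reads`, and it is not confined to a homopolymer mask.
#' A read is edited when it carries at least one qualifying pattern; each
#' read counts once however many qualifying patterns it carries.
#'
#' @param table a [build_pattern_table()] result.
#' @param cfg an [edit_call_config()].
#' @param masks mask intervals (matrix from [detect_homopolymer_masks()] or
#'   an [amplicon_ref()], whose masks are then used); `NULL` for none.
#' @return an object of class `edit_result`: `edited_reads`, `total_reads`,
#'   `efficiency`, `percent` (2 significant figures),
#'   `qualifying_patterns`, `excluded_patterns` (with `reason`).
#' @export
classify_edited <- function(table, cfg = edit_call_config(), masks = NULL) {
  stopifnot(inherits(table, "pattern_table"))
  if (inherits(masks, "amplicon_ref")) masks <- masks$mask_intervals
  cc <- table$counts
  if (nrow(cc) == 0L) {
    if (table$total_reads == 0L)
      warning("empty pattern table: no aligned reads", call. = FALSE)
    return(.edit_result(0L, table$total_reads, cc, cc))
  }
  reason <- character(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    r <- character()
    if (cc$size[i] < cfg$min_indel_size) r <- c(r, "min_size")
    if (cc$count[i] < cfg$min_pattern_reads) r <- c(r, "min_count")
    if (.pattern_masked(cc$kind[i], cc$start[i], cc$size[i],
                        cc$ambiguity_end[i], masks)) r <- c(r, "mask")
    reason[i] <- paste(r, collapse = ",")
  }
  qualifies <- reason == ""
  qual_keys <- cc$key[qualifies]
  edited <- 0L
  for (i in seq_along(table$read_keys)) {
    if (any(table$read_keys[[i]] %in% qual_keys))
      edited <- edited + table$read_weights[i]
  }
  excluded <- cc[!qualifies, , drop = FALSE]
  excluded$reason <- reason[!qualifies]
  .edit_result(edited, table$total_reads,
               cc[qualifies, , drop = FALSE], excluded)
}

.edit_result <- function(edited, total, qualifying, excluded) {
  eff <- if (total > 0L) edited / total else 0
  structure(list(edited_reads = as.integer(edited),
                 total_reads = as.integer(total),
                 efficiency = eff,
                 percent = signif(100 * eff, 2),
                 qualifying_patterns = qualifying,
                 excluded_patterns = excluded),
            class = "edit_result")
}

#' @export
print.edit_result <- function(x, ...) {
  cat(sprintf("editing efficiency: %s%% (%s edited reads / %s total reads)\n",
              format(x$percent), format(x$edited_reads, big.mark = ","),
              format(x$total_reads, big.mark = ",")))
  cat(sprintf("  %d qualifying pattern(s), %d excluded\n",
              nrow(x$qualifying_patterns), nrow(x$excluded_patterns)))
  invisible(x)
}

#' Editing efficiency with the 2-significant-figure report rule
#'
#' The exact fraction `edited / total` is retained; the human-readable
#' report value is the percentage rounded to two significant figures
#' (e.g. 79,768 / 9,404,589 reports as 0.85%).
#'
#' @param edited,total edited and total read counts, `0 <= edited <= total`,
#'   `total > 0`.
#' @return list with `fraction` and `percent` (2 significant figures).
#' @examples
#' editing_efficiency(79768, 9404589)$percent  # 0.85
#' @export
editing_efficiency <- function(edited, total) {
  if (!is.numeric(total) || total <= 0)
    stop("total must be positive: efficiency undefined", call. = FALSE)
  if (edited < 0 || edited > total)
    stop("edited must lie in [0, total]", call. = FALSE)
  frac <- edited / total
  list(fraction = frac, percent = signif(100 * frac, 2))
}

#' Deletion-size profile of qualifying patterns
#'
#' Histogram of deletion sizes over the qualifying patterns of an
#' [classify_edited()] result, weighted by read counts. Insertions never
#' contribute. Staggered-cut repair is expected to put the mode around
#' 8-10 bp.
#'
#' @param result an `edit_result`.
#' @return data.frame with columns `size` and `count`, sorted by size.
#' @export
deletion_size_profile <- function(result) {
  stopifnot(inherits(result, "edit_result"))
  qp <- result$qualifying_patterns
  qp <- qp[qp$kind == "deletion", , drop = FALSE]
  if (nrow(qp) == 0L)
    return(data.frame(size = integer(), count = integer()))
  agg <- tapply(qp$count, qp$size, sum)
  data.frame(size = as.integer(names(agg)), count = as.integer(agg),
             row.names = NULL)[order(as.integer(names(agg))), , drop = FALSE]
}

#' Normalize per-sample efficiencies to a reference group
#'
#' Expresses each sample's editing efficiency as a ratio over the mean
#' efficiency of a reference sample group (e.g. the wild-type nuclease),
#' so construct variants can be compared across experiments. The reference
#' group's own ratios average exactly 1.
#'
#' @param efficiencies named numeric vector of per-sample fractions.
#' @param reference_group names (or indices) of the reference samples.
#' @return named numeric vector of ratios.
#' @export
normalize_to_reference <- function(efficiencies, reference_group) {
  stopifnot(is.numeric(efficiencies))
  refvals <- efficiencies[reference_group]
  if (length(refvals) == 0L || anyNA(refvals))
    stop("reference group empty or missing from efficiencies", call. = FALSE)
  m <- mean(refvals)
  if (m <= 0) stop("reference group mean is zero: ratios undefined",
                   call. = FALSE)
  efficiencies / m
}
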