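#' Build a pattern table from per-read indel events
#'
#' Aggregates left-normalized indel events into mutation patterns. Pattern
#' identity is `(kind, size, start)` — indels of the same size starting at
#' the same (left-normalized) location are the same pattern; inserted or
#' deleted sequence content is not part of the identity. A read carrying k
#' distinct events increments k patterns but is still a single read in
#' `total_reads`.
#'
#' @param events_by_read list with one [extract_indels()] data.frame per
#'   (unique) read; reads without indels contribute an empty data.frame.
#' @param n_total total number of aligned reads (the efficiency
#'   denominator). Defaults to the (weighted) number of reads supplied.
#' @param weights read multiplicities, for tables built from unique read
#'   sequences; defaults to 1 per entry.
#' @return an object of class `pattern_table`: `counts` (data.frame with
#'   `key`, `kind`, `size`, `start`, `ambiguity_end`, `count`),
#'   `total_reads`, and `read_keys`/`read_weights` mapping reads to the
#'   patterns they carry.
#' @export
build_pattern_table <- function(events_by_read, n_total = NULL, weights = NULL) {
  stopifnot(is.list(events_by_read))
  nr <- length(events_by_read)
  if (is.null(weights)) weights <- rep(1L, nr)
  stopifnot(length(weights) == nr, all(weights >= 0))
  if (is.null(n_total)) n_total <- sum(weights)

  read_keys <- vector("list", nr)
  all_rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    ev <- events_by_read[[i]]
    if (is.null(ev) || nrow(ev) == 0L) {
      read_keys[[i]] <- character()
      next
    }
    if (any(ev$start > ev$ambiguity_end))
      stop("un-normalized event detected (start > ambiguity_end)", call. = FALSE)
    key <- paste(ev$kind, ev$size, ev$start, sep = ":")
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      ev <- ev[keep, , drop = FALSE]
      key <- key[keep]
    }
    read_keys[[i]] <- key
    all_rows[[i]] <- data.frame(key = key, kind = ev$kind, size = ev$size,
                                start = ev$start,
                                ambiguity_end = ev$ambiguity_end,
                                weight = weights[i], stringsAsFactors = FALSE)
  }

  rows <- do.call(rbind, all_rows)
  if (is.null(rows)) {
    counts <- data.frame(key = character(), kind = character(),
                         size = integer(), start = integer(),
                         ambiguity_end = integer(), count = integer(),
                         stringsAsFactors = FALSE)
  } else {
    count <- tapply(rows$weight, rows$key, sum)
    amb <- tapply(rows$ambiguity_end, rows$key, max)
    first <- rows[!duplicated(rows$key), c("key", "kind", "size", "start")]
    first <- first[order(first$key), , drop = FALSE]
    counts <- data.frame(first,
                         ambiguity_end = as.integer(amb[first$key]),
                         count = as.integer(count[first$key]),
                         stringsAsFactors = FALSE)
    counts <- counts[order(counts$start, counts$size, counts$kind), ,
                     drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(list(counts = counts, total_reads = as.integer(n_total),
                 read_keys = read_keys, read_weights = as.integer(weights)),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf("pattern table: %d pattern(s) over %d aligned read(s)\n",
              nrow(x$counts), x$total_reads))
  if (nrow(x$counts)) print(utils::head(x$counts[order(-x$counts$count), ], 10))
  invisible(x)
}
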