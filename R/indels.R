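#' Detect homopolymer mask intervals
#'
#' Finds all maximal single-base runs of length `>= min_run` (any base) and
#' returns them as sorted, non-overlapping, 0-based half-open intervals.
#' These are the error-prone stretches — in practice long adenine runs near
#' some targets — within which indels are not trusted as edits.
#'
#' @param ref reference sequence (character).
#' @param min_run minimum run length (>= 2); a run exactly `min_run` long is
#'   included.
#' @return integer matrix with columns `start`, `end`.
#' @examples
#' detect_homopolymer_masks("CCAAAAAAAAGG", min_run = 8)  # one interval (2,10)
#' @export
detect_homopolymer_masks <- function(ref, min_run = 8L) {
  min_run <- .check_count(min_run, "min_run", min = 2L)
  ref <- .check_dna(ref, "ref", allow_n = TRUE)
  r <- rle(strsplit(ref, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_run
  m <- cbind(start = starts[keep], end = ends[keep])
  storage.mode(m) <- "integer"
  m
}

# Left-normalize a deletion of `size` bases starting at 0-based `start`:
# shift to the smallest start yielding an identical alternate sequence, and
# record the rightmost equivalent start (ambiguity_end).
.normalize_deletion <- function(refchars, start, size) {
  n <- length(refchars)
  s <- start
  while (s > 0L && refchars[s] == refchars[s + size]) s <- s - 1L
  e <- s
  while (e + size < n && refchars[e + 1L] == refchars[e + size + 1L]) e <- e + 1L
  list(start = s, ambiguity_end = e,
       seq = paste(refchars[(s + 1L):(s + size)], collapse = ""))
}

# Left-normalize an insertion of `seq` before 0-based reference position
# `start`; the inserted sequence rotates as the event shifts.
.normalize_insertion <- function(refchars, start, seq) {
  v <- strsplit(seq, "")[[1]]
  k <- length(v)
  n <- length(refchars)
  s <- start
  while (s > 0L && refchars[s] == v[k]) {
    v <- c(refchars[s], v[-k])
    s <- s - 1L
  }
  # rightmost equivalent placement (sequence content at that placement differs
  # by rotation; only the coordinate is recorded)
  e <- s; w <- v
  while (e < n && refchars[e + 1L] == w[1L]) {
    w <- c(w[-1L], refchars[e + 1L])
    e <- e + 1L
  }
  list(start = s, ambiguity_end = e, seq = paste(v, collapse = ""))
}

.empty_events <- function() {
  data.frame(kind = character(), start = integer(), size = integer(),
             seq = character(), ambiguity_end = integer(),
             stringsAsFactors = FALSE)
}

#' Extract left-normalized indel events from an alignment
#'
#' Walks a gapped read/reference alignment, emits one event per maximal gap
#' run, and left-normalizes every event (shifting it to the smallest
#' reference start that yields an identical alternate sequence). The
#' rightmost equivalent start is kept as `ambiguity_end`, which downstream
#' masking uses: an indel "sits inside" a homopolymer only if its whole
#' ambiguity range does.
#'
#' @param alignment an alignment from [align_read()] (or any list with
#'   gapped `pattern` (read) and `subject` (reference) strings).
#' @param ref the reference amplicon as a character string or
#'   [amplicon_ref()]; defaults to the alignment's own reference.
#' @return data.frame with columns `kind` ("insertion"/"deletion"), `start`
#'   (0-based, left-normalized), `size`, `seq`, `ambiguity_end`.
#' @export
extract_indels <- function(alignment, ref = NULL) {
  pat <- strsplit(alignment$pattern, "")[[1]]
  sub <- strsplit(alignment$subject, "")[[1]]
  if (length(pat) != length(sub))
    stop("gapped strings differ in length: not a valid alignment", call. = FALSE)
  if (is.null(ref)) ref <- alignment$ref
  if (inherits(ref, "amplicon_ref")) ref <- ref$sequence
  refchars <- strsplit(ref, "")[[1]]

  is_del <- pat == "-"   # read missing reference bases
  is_ins <- sub == "-"   # extra read bases
  if (any(is_del & is_ins)) stop("alignment column with two gaps", call. = FALSE)
  events <- .empty_events()
  refpos <- 0L  # reference bases consumed so far
  i <- 1L
  n <- length(pat)
  while (i <= n) {
    if (is_del[i]) {
      j <- i
      while (j < n && is_del[j + 1L]) j <- j + 1L
      size <- j - i + 1L
      nm <- .normalize_deletion(refchars, refpos, size)
      events <- rbind(events, data.frame(
        kind = "deletion", start = nm$start, size = size, seq = nm$seq,
        ambiguity_end = nm$ambiguity_end, stringsAsFactors = FALSE))
      refpos <- refpos + size
      i <- j + 1L
    } else if (is_ins[i]) {
      j <- i
      while (j < n && is_ins[j + 1L]) j <- j + 1L
      seq <- paste(pat[i:j], collapse = "")
      nm <- .normalize_insertion(refchars, refpos, seq)
      events <- rbind(events, data.frame(
        kind = "insertion", start = nm$start, size = j - i + 1L, seq = nm$seq,
        ambiguity_end = nm$ambiguity_end, stringsAsFactors = FALSE))
      i <- j + 1L
    } else {
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }
  events
}
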