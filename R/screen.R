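#' Variant screening configuration
#'
#' Thresholds of the off-target screening cascade. Hard filters follow
#' standard short-read practice: SNPs fail on QD < 2.0, FS > 60.0,
#' MQ < 40.0 or SOR > 4.0; indels fail on QD < 2.0, FS > 200.0 or
#' SOR > 10.0 (no MQ criterion). Variants with coverage below
#' `min_coverage` reads, or with more than `max_ref_alt_ratio` reference
#' reads per variant read, are removed (both comparisons strict, as
#' written: "lower than 30" and "larger than three"). Simple-repeat
#' masking removes variants confined to mononucleotide runs of
#' `repeat_mono_min` bp or dinucleotide tandems of `repeat_di_min` units —
#' a deterministic replacement for manual inspection, so the run-length
#' defaults are this package's choice. `offtarget_window` pads predicted
#' protospacer spans when intersecting surviving variants with them, to
#' catch staggered-cut junction variants just outside the protospacer.
#'
#' @param snp_thresholds,indel_thresholds named lists of hard-filter
#'   thresholds.
#' @param min_coverage minimum reads covering the variant (default 30).
#' @param max_ref_alt_ratio maximum Ref/Alt read ratio (default 3).
#' @param repeat_mono_min,repeat_di_min simple-repeat definitions (bp /
#'   units).
#' @param offtarget_window padding around predicted sites (bp).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(snp_thresholds = list(QD_min = 2.0, FS_max = 60.0,
                                                MQ_min = 40.0, SOR_max = 4.0),
                          indel_thresholds = list(QD_min = 2.0, FS_max = 200.0,
                                                  SOR_max = 10.0),
                          min_coverage = 30L, max_ref_alt_ratio = 3.0,
                          repeat_mono_min = 10L, repeat_di_min = 6L,
                          offtarget_window = 20L) {
  stopifnot(min_coverage > 0, max_ref_alt_ratio > 0,
            repeat_mono_min >= 2, repeat_di_min >= 2, offtarget_window >= 0)
  structure(list(snp_thresholds = snp_thresholds,
                 indel_thresholds = indel_thresholds,
                 min_coverage = as.integer(min_coverage),
                 max_ref_alt_ratio = max_ref_alt_ratio,
                 repeat_mono_min = as.integer(repeat_mono_min),
                 repeat_di_min = as.integer(repeat_di_min),
                 offtarget_window = as.integer(offtarget_window)),
            class = "screen_config")
}

.variant_cols <- c("chrom", "pos", "ref", "alt", "vtype", "ad_ref", "ad_alt",
                   "dp", "qd", "fs", "mq", "sor", "caller")

.empty_variants <- function() {
  df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), vtype = character(), ad_ref = integer(),
                   ad_alt = integer(), dp = integer(), qd = numeric(),
                   fs = numeric(), mq = numeric(), sor = numeric(),
                   caller = character(), key = character(),
                   stringsAsFactors = FALSE)
  df
}

.variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Normalize raw variant records
#'
#' Splits multiallelic records into one row per (chrom, pos, ref, alt),
#' apportioning comma-separated allele depths to their alleles, derives the
#' variant type (`SNP` when both alleles are single bases, else `indel`),
#' deduplicates identical records, and attaches the identity `key` used by
#' every set operation downstream. Malformed rows (empty or non-ACGT
#' ref/alt, ref equal to alt) are dropped and returned in the `"rejected"`
#' attribute.
#'
#' @param records data.frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   optional `ad_ref`, `ad_alt` (comma-separated for multiallelics), `dp`,
#'   `qd`, `fs`, `mq`, `sor`, `caller`.
#' @return normalized data.frame (class `variant_set`).
#' @export
split_and_key <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  for (col in setdiff(.variant_cols, names(records))) {
    records[[col]] <- if (col %in% c("chrom", "ref", "alt", "vtype", "caller"))
      rep(NA_character_, n) else rep(NA_real_, n)
  }
  out <- list()
  rejected <- list()
  for (i in seq_len(n)) {
    alts <- strsplit(toupper(as.character(records$alt[i])), ",")[[1]]
    ref <- toupper(as.character(records$ref[i]))
    ads <- strsplit(as.character(records$ad_alt[i]), ",")[[1]]
    for (j in seq_along(alts)) {
      alt <- alts[j]
      bad <- is.na(ref) || is.na(alt) || nchar(ref) == 0L || nchar(alt) == 0L ||
        grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt) || identical(ref, alt)
      row <- data.frame(
        chrom = as.character(records$chrom[i]),
        pos = as.integer(records$pos[i]), ref = ref, alt = alt,
        vtype = if (!bad && nchar(ref) == 1L && nchar(alt) == 1L) "SNP"
                else "indel",
        ad_ref = as.integer(records$ad_ref[i]),
        ad_alt = suppressWarnings(as.integer(ads[min(j, length(ads))])),
        dp = as.integer(records$dp[i]), qd = as.numeric(records$qd[i]),
        fs = as.numeric(records$fs[i]), mq = as.numeric(records$mq[i]),
        sor = as.numeric(records$sor[i]),
        caller = as.character(records$caller[i]), stringsAsFactors = FALSE)
      if (bad) rejected[[length(rejected) + 1L]] <- cbind(
        row, reason = "malformed ref/alt")
      else out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- .empty_variants()
  else {
    out$key <- .variant_key(out)
    out <- out[!duplicated(out$key), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected)
                           else NULL
  class(out) <- c("variant_set", "data.frame")
  out
}

.ensure_keyed <- function(x) {
  if (is.null(x$key)) x <- split_and_key(x)
  x
}

#' Intersect two caller call sets
#'
#' Keeps variants whose (chrom, pos, ref, alt) key was called by both
#' callers; depths and annotations are taken from the first (primary) call
#' set, provenance notes both callers.
#'
#' @param a,b normalized variant sets ([split_and_key()]).
#' @return the intersection, rows from `a`.
#' @export
intersect_callsets <- function(a, b) {
  a <- .ensure_keyed(a); b <- .ensure_keyed(b)
  out <- a[a$key %in% b$key, , drop = FALSE]
  if (nrow(out)) {
    ca <- ifelse(is.na(out$caller), "A", out$caller)
    cb <- unique(b$caller); cb <- cb[!is.na(cb)]
    out$caller <- paste(ca, if (length(cb)) paste(cb, collapse = "+")
                        else "B", sep = "+")
  }
  rownames(out) <- NULL
  out
}

#' Apply GATK-style hard filters
#'
#' Removes SNPs failing any SNP threshold and indels failing any indel
#' threshold. A record lacking a given annotation passes that criterion —
#' intersection already required both callers to agree, and annotations are
#' only defined where the primary caller emitted them.
#'
#' @param records normalized variant set.
#' @param cfg a [screen_config()].
#' @return the surviving records.
#' @export
apply_hard_filters <- function(records, cfg = screen_config()) {
  records <- .ensure_keyed(records)
  if (nrow(records) == 0L) return(records)
  s <- cfg$snp_thresholds; ind <- cfg$indel_thresholds
  fails <- function(x, thr, dir) !is.na(x) & if (dir == "min") x < thr
                                             else x > thr
  is_snp <- records$vtype == "SNP"
  bad_snp <- is_snp & (fails(records$qd, s$QD_min, "min") |
                       fails(records$fs, s$FS_max, "max") |
                       fails(records$mq, s$MQ_min, "min") |
                       fails(records$sor, s$SOR_max, "max"))
  bad_ind <- !is_snp & (fails(records$qd, ind$QD_min, "min") |
                        fails(records$fs, ind$FS_max, "max") |
                        fails(records$sor, ind$SOR_max, "max"))
  out <- records[!(bad_snp | bad_ind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract background-line variants
#'
#' Removes every record whose (chrom, pos, ref, alt) key also occurs in the
#' background call set (the untransformed parental line), leaving only
#' variants that arose in the edited plants.
#'
#' @param records,background normalized variant sets.
#' @return the surviving records.
#' @export
subtract_background <- function(records, background) {
  records <- .ensure_keyed(records)
  if (is.null(background) || nrow(background) == 0L) {
    warning("empty background call set: nothing subtracted", call. = FALSE)
    return(records)
  }
  background <- .ensure_keyed(background)
  out <- records[!records$key %in% background$key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage and allele-balance filter
#'
#' Keeps a variant iff its coverage (`ad_ref + ad_alt` when allele depths
#' are present, else `dp`) is at least `min_coverage`, it has at least one
#' variant-supporting read, and the Ref/Alt read ratio is at most
#' `max_ref_alt_ratio`. Zero variant reads count as an infinite ratio.
#' Records with neither AD nor DP are removed (reason in the `"rejected"`
#' attribute). This is the heterozygote-selection step whose miss
#' probability [het_detection_power()] computes.
#'
#' @param records normalized variant set.
#' @param cfg a [screen_config()].
#' @return the surviving records.
#' @export
depth_and_ratio_filter <- function(records, cfg = screen_config()) {
  records <- .ensure_keyed(records)
  if (nrow(records) == 0L) return(records)
  has_ad <- !is.na(records$ad_ref) & !is.na(records$ad_alt)
  cov <- ifelse(has_ad, records$ad_ref + records$ad_alt, records$dp)
  no_depth <- is.na(cov)
  ratio_ok <- has_ad & records$ad_alt > 0 &
    records$ad_ref / pmax(records$ad_alt, 1L) <= cfg$max_ref_alt_ratio
  # without AD the ratio criterion cannot be evaluated and passes
  ratio_ok <- ratio_ok | (!has_ad & !no_depth)
  keep <- !no_depth & cov >= cfg$min_coverage & ratio_ok
  out <- records[keep, , drop = FALSE]
  rej <- records[no_depth, , drop = FALSE]
  attr(out, "rejected") <- if (nrow(rej)) cbind(rej, reason = "no AD or DP")
                           else NULL
  rownames(out) <- NULL
  out
}

#' Probability that the allele-balance filter misses a true heterozygote
#'
#' For a heterozygous variant covered by `n` reads, the variant-read count
#' K is Binomial(n, 1/2); the variant is discarded when the reference/
#' variant ratio exceeds `ratio_cutoff`, i.e. when
#' K < n / (ratio_cutoff + 1). This closed-form one-tailed probability is
#' the power cost of the Ref/Alt filter: at 30x coverage and cutoff 3 it is
#' 0.0026 (0.26%), and it decreases with coverage.
#'
#' @param n coverage (reads), >= 1. Vectorized.
#' @param ratio_cutoff maximum tolerated Ref/Alt ratio (default 3).
#' @return probability of discarding a true heterozygote.
#' @examples
#' het_detection_power(30, 3)  # 0.0026
#' @export
het_detection_power <- function(n, ratio_cutoff = 3) {
  stopifnot(all(n >= 1), ratio_cutoff > 0)
  k_max <- ceiling(n / (ratio_cutoff + 1)) - 1
  stats::pbinom(k_max, n, 0.5)
}

# simple-repeat intervals (0-based half-open) of one chromosome:
# mononucleotide runs >= mono_min bp and perfect dinucleotide tandems of
# >= di_min units (extended to maximal phase on both sides)
.repeat_intervals <- function(seq, mono_min, di_min) {
  mono <- detect_homopolymer_masks(seq, mono_min)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  di <- matrix(integer(), ncol = 2L)
  m <- gregexpr("([ACGT]{2})\\1+", seq, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    rows <- list()
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- s + lens[k]
      # extend to maximal period-2 context
      while (s > 0L && chars[s] == chars[s + 2L]) s <- s - 1L
      while (e < n && chars[e + 1L] == chars[e - 1L]) e <- e + 1L
      if (chars[s + 1L] != chars[s + 2L] && (e - s) >= 2L * di_min)
        rows[[length(rows) + 1L]] <- c(s, e)
    }
    if (length(rows)) di <- do.call(rbind, rows)
  }
  out <- rbind(mono, di)
  colnames(out) <- c("start", "end")
  out[order(out[, 1]), , drop = FALSE]
}

# 0-based half-open genomic interval a variant occupies, extended over its
# left-normalization ambiguity range (anchored VCF representation assumed)
.variant_interval <- function(chrom_chars, pos, ref, alt) {
  n <- length(chrom_chars)
  if (pos < 1L || pos + nchar(ref) - 1L > n)
    stop("variant at position ", pos, " lies outside the genome", call. = FALSE)
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(c(pos - 1L, pos))  # SNP
  if (nchar(ref) > nchar(alt)) {       # deletion of ref[2..] after anchor
    size <- nchar(ref) - nchar(alt)
    nm <- .normalize_deletion(chrom_chars, pos, size)  # event starts at pos (0-based)
    c(nm$start, nm$ambiguity_end + size)
  } else {                             # insertion after anchor base
    ins <- substr(alt, 2L, nchar(alt))
    nm <- .normalize_insertion(chrom_chars, pos, ins)
    c(nm$start, max(nm$ambiguity_end, nm$start + 1L))
  }
}

#' Remove variants confined to simple repeats
#'
#' Deterministic triage of calls in low-complexity context: a variant is
#' removed when its genomic interval, extended over its left-normalization
#' ambiguity range, lies entirely within one mononucleotide run of at least
#' `repeat_mono_min` bp or one perfect dinucleotide tandem of at least
#' `repeat_di_min` units. Variants merely overlapping a repeat edge are
#' kept.
#'
#' @param records normalized variant set.
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param cfg a [screen_config()].
#' @return the surviving records.
#' @export
simple_repeat_filter <- function(records, genome, cfg = screen_config()) {
  records <- .ensure_keyed(records)
  if (nrow(records) == 0L) return(records)
  genome <- .as_genome(genome)
  keep <- logical(nrow(records))
  for (chrom in unique(records$chrom)) {
    if (!chrom %in% names(genome))
      stop("chromosome ", chrom, " absent from the genome", call. = FALSE)
    idx <- which(records$chrom == chrom)
    chars <- strsplit(genome[[chrom]], "")[[1]]
    reps <- .repeat_intervals(genome[[chrom]], cfg$repeat_mono_min,
                              cfg$repeat_di_min)
    for (i in idx) {
      iv <- .variant_interval(chars, records$pos[i], records$ref[i],
                              records$alt[i])
      contained <- nrow(reps) > 0L &&
        any(reps[, 1] <= iv[1] & iv[2] <= reps[, 2])
      keep[i] <- !contained
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect surviving variants with predicted off-target sites
#'
#' Labels each variant with every predicted site whose protospacer span,
#' padded by `window` bp on each side, contains the variant position.
#'
#' @param records normalized variant set.
#' @param sites data.frame from [find_sites()] (may be empty).
#' @param window padding in bp (default from [screen_config()]).
#' @return list with `overlaps` (data.frame of variant/site pairs) and
#'   `n_overlap` (number of overlapping variants).
#' @export
annotate_offtarget_overlap <- function(records, sites,
                                       window = screen_config()$offtarget_window) {
  records <- .ensure_keyed(records)
  empty <- data.frame(key = character(), chrom = character(), pos = integer(),
                      site_start = integer(), site_end = integer(),
                      site_strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L || is.null(sites) || nrow(sites) == 0L)
    return(list(overlaps = empty, n_overlap = 0L))
  vr <- GenomicRanges::GRanges(records$chrom,
                               IRanges::IRanges(records$pos, records$pos))
  sr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(pmax(1L, sites$start + 1L - window),
                                                sites$end + window))
  ov <- GenomicRanges::findOverlaps(vr, sr)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  overlaps <- data.frame(key = records$key[qi], chrom = records$chrom[qi],
                         pos = records$pos[qi], site_start = sites$start[si],
                         site_end = sites$end[si],
                         site_strand = sites$strand[si],
                         mismatches = sites$mismatches[si],
                         stringsAsFactors = FALSE)
  list(overlaps = overlaps, n_overlap = length(unique(qi)))
}

#' Run the full off-target screening cascade
#'
#' Normalizes both caller call sets and the background set, intersects the
#' callers, applies the hard filters, subtracts the background, applies the
#' coverage/allele-balance filter, removes simple-repeat variants, and
#' intersects the survivors with predicted off-target sites. Stage counts
#' are non-increasing from the intersection onward.
#'
#' @param a,b variant data.frames from the two callers.
#' @param background background-line variant data.frame.
#' @param genome reference genome (for the repeat filter).
#' @param sites predicted off-target sites from [find_sites()]; `NULL`
#'   skips overlap annotation.
#' @param cfg a [screen_config()].
#' @return object of class `screen_report`: `stages` (stage, n), `variants`
#'   (final set, with SNP/indel split in `summary`), `overlaps`.
#' @export
screen_variants <- function(a, b, background, genome, sites = NULL,
                            cfg = screen_config()) {
  a <- .ensure_keyed(a); b <- .ensure_keyed(b)
  background <- .ensure_keyed(background)
  stages <- list()
  note <- function(stage, x) stages[[length(stages) + 1L]] <<-
    data.frame(stage = stage, n = nrow(x), stringsAsFactors = FALSE)
  note("caller_A", a); note("caller_B", b)
  x <- intersect_callsets(a, b); note("intersection", x)
  x <- apply_hard_filters(x, cfg); note("hard_filters", x)
  x <- subtract_background(x, background); note("background_subtracted", x)
  x <- depth_and_ratio_filter(x, cfg); note("depth_and_ratio", x)
  x <- simple_repeat_filter(x, genome, cfg); note("simple_repeats", x)
  ov <- annotate_offtarget_overlap(x, sites, cfg$offtarget_window)
  structure(list(
    stages = do.call(rbind, stages),
    variants = x,
    summary = c(SNP = sum(x$vtype == "SNP"), indel = sum(x$vtype == "indel")),
    overlaps = ov$overlaps, n_overlap = ov$n_overlap), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("off-target screening cascade:\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final: %d variant(s) (%d SNP, %d indel); %d overlapping predicted sites\n",
              nrow(x$variants), x$summary[["SNP"]], x$summary[["indel"]],
              x$n_overlap))
  invisible(x)
}
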