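#' @name offtarget
#' @title Genome-wide off-target site search
#'
#' @description
#' Enumerates candidate off-target loci for a spacer: every genomic window
#' (both strands) whose 5'-adjacent triplet satisfies the PAM rule and whose
#' best spacer alignment stays within the mismatch and bulge budgets. A DNA
#' bulge is an extra protospacer base (gap in the spacer), an RNA bulge an
#' extra spacer base (gap in the protospacer); the bulge budget bounds the
#' size of a single contiguous bulge of either type (scattered or
#' opposite-type bulge pairs are not admitted — they do not correspond to a
#' real guide-target duplex geometry). Bulges are internal to the spacer
#' alignment and never inside the PAM. The reported alignment minimizes
#' (mismatches + bulged bases), with ties broken by fewer bulged bases, then
#' by type (RNA-bulge layout preferred), then leftmost bulge placement.
#'
#' `find_sites()` is the production path (PAM pre-scan plus a constrained
#' dynamic program in C); `site_oracle()` is an independent brute-force
#' enumeration of every bulge layout at every PAM-anchored window, kept to
#' test scale, that defines ground truth for `find_sites()`.
NULL

.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- as.character(Biostrings::readDNAStringSet(genome))
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == ""))
    stop("genome must be a named character vector, DNAStringSet or FASTA path",
         call. = FALSE)
  setNames(toupper(genome), names(genome))
}

.empty_sites <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), strand = character(), mismatches = integer(),
             dna_bulge = integer(), rna_bulge = integer(),
             pam_seq = character(), aligned_spacer = character(),
             aligned_protospacer = character(), stringsAsFactors = FALSE)
}

# All single-bulge layouts with <= max_bulge bulged bases for a spacer of
# length L: one contiguous bulge of one type (the cited prediction tools'
# convention — scattered or opposite-type bulge pairs could excise
# mismatches and are not real duplex geometries). DNA bulge positions are
# "after spacer base p" (p in 1..L-1; a 2 bp bulge is two bases at one
# junction); RNA bulge positions are skipped spacer bases (2..L-1,
# adjacent when 2 bp). `offsets[i]` maps spacer base i to its 0-based
# window offset (NA when skipped).
.bulge_configs <- function(L, max_bulge) {
  raw <- list(list(dna = integer(), rna = integer()))
  add <- function(dna, rna) raw[[length(raw) + 1L]] <<- list(dna = dna, rna = rna)
  if (max_bulge >= 1L && L >= 2L) {
    for (p in 1:(L - 1L)) add(p, integer())
    if (L >= 3L) for (q in 2:(L - 1L)) add(integer(), q)
  }
  if (max_bulge >= 2L && L >= 2L) {
    for (p in 1:(L - 1L)) add(c(p, p), integer())
    if (L >= 4L) for (q in 2:(L - 2L)) add(integer(), c(q, q + 1L))
  }
  lapply(raw, function(cf) {
    d <- length(cf$dna); r <- length(cf$rna)
    off <- integer(L)
    for (i in seq_len(L))
      off[i] <- (i - 1L) - sum(cf$rna < i) + sum(cf$dna < i)
    if (r) off[cf$rna] <- NA_integer_
    list(dna = cf$dna, rna = cf$rna, d = d, r = r, offsets = off,
         W = L + d - r, possum = sum(cf$dna) + sum(cf$rna))
  })
}

# canonical preference encoded as one number (smaller is better)
.layout_score <- function(mm, d, r, possum) {
  (((mm + d + r) * 64 + d + r) * 8 + d) * 64 + possum
}

# pure-R PAM scan: 0-based PAM start positions; genome N only matches rule N
.pam_anchors_r <- function(chars, rule) {
  P <- nchar(rule); n <- length(chars)
  if (n < P) return(integer())
  rb <- strsplit(rule, "")[[1]]
  ok <- rep(TRUE, n - P + 1L)
  for (k in seq_len(P)) {
    gk <- chars[k:(n - P + k)]
    okk <- gk %in% .iupac[[rb[k]]] & gk != "N"
    if (rb[k] == "N") okk <- okk | gk == "N"
    ok <- ok & okk
  }
  which(ok) - 1L
}

# gapped spacer/protospacer strings for one layout at one window
.render_alignment <- function(windowchars, spacer, cf) {
  sp <- strsplit(spacer, "")[[1]]
  L <- length(sp)
  s_out <- character(0); w_out <- character(0); j <- 0L
  for (i in seq_len(L)) {
    if (i %in% cf$rna) {
      s_out <- c(s_out, sp[i]); w_out <- c(w_out, "-")
    } else {
      j <- j + 1L
      s_out <- c(s_out, sp[i]); w_out <- c(w_out, windowchars[j])
    }
    nb <- sum(cf$dna == i)
    while (nb > 0L) {
      j <- j + 1L
      s_out <- c(s_out, "-"); w_out <- c(w_out, windowchars[j])
      nb <- nb - 1L
    }
  }
  c(spacer = paste(s_out, collapse = ""),
    protospacer = paste(w_out, collapse = ""))
}

# canonical best layout for a single anchor, by enumeration
.best_layout <- function(chars, proto0, spacer, configs, max_mm, max_bulge) {
  sp <- strsplit(spacer, "")[[1]]
  glen <- length(chars)
  best <- Inf; bestcf <- NULL; bestmm <- NA_integer_
  for (cf in configs) {
    if (cf$d + cf$r > max_bulge) next
    if (proto0 + cf$W > glen) next
    mm <- 0L
    for (i in seq_along(sp)) {
      if (is.na(cf$offsets[i])) next
      if (chars[proto0 + cf$offsets[i] + 1L] != sp[i]) mm <- mm + 1L
    }
    if (mm > max_mm) next
    sc <- .layout_score(mm, cf$d, cf$r, cf$possum)
    if (sc < best) { best <- sc; bestcf <- cf; bestmm <- mm }
  }
  if (is.null(bestcf)) return(NULL)
  list(cf = bestcf, mm = bestmm)
}

.strand_coords <- function(p0, W, glen, strand) {
  if (strand == "+") c(p0, p0 + W) else c(glen - (p0 + W), glen - p0)
}

#' @rdname offtarget
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param spacer spacer sequence (10-30 nt).
#' @param rule 5' PAM rule as an IUPAC string (default `"TBN"`).
#' @param max_mismatch mismatch budget (default 4).
#' @param max_bulge total bulged-base budget across both types (default 2;
#'   at most 2 supported).
#' @return data.frame of candidate sites: `chrom`, `start`, `end` (0-based
#'   half-open protospacer span), `name` (the spacer), `strand`,
#'   `mismatches`, `dna_bulge`, `rna_bulge`, `pam_seq`, `aligned_spacer`,
#'   `aligned_protospacer`; sorted by locus.
#' @export
find_sites <- function(genome, spacer, rule = "TBN", max_mismatch = 4L,
                       max_bulge = 2L) {
  genome <- .as_genome(genome)
  spacer <- .check_dna(spacer, "spacer")
  if (nchar(spacer) < 10L) stop("spacer must be at least 10 nt", call. = FALSE)
  stopifnot(max_mismatch >= 0L, max_bulge >= 0L)
  if (max_bulge > 2L) stop("bulge budgets above 2 bp are not supported",
                           call. = FALSE)
  configs <- .bulge_configs(nchar(spacer), max_bulge)
  rows <- list()
  P <- nchar(rule)
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") genome[[chrom]] else .revcomp(genome[[chrom]])
      glen <- nchar(seq)
      anchors <- .pam_scan_cpp(seq, rule)
      if (length(anchors) == 0L) next
      proto0 <- anchors + P
      hits <- .spacer_align_anchors_cpp(seq, proto0, spacer,
                                        as.integer(max_mismatch),
                                        as.integer(max_bulge))
      keep <- which(hits$feasible)
      if (length(keep) == 0L) next
      chars <- strsplit(seq, "")[[1]]
      for (k in keep) {
        p0 <- hits$proto_start[k]
        W <- hits$span[k]
        lay <- .best_layout(chars, p0, spacer, configs, max_mismatch, max_bulge)
        aln <- .render_alignment(chars[(p0 + 1L):(p0 + W)], spacer, lay$cf)
        co <- .strand_coords(p0, W, glen, strand)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = co[1], end = co[2], name = spacer,
          strand = strand, mismatches = hits$mismatches[k],
          dna_bulge = hits$dna_bulge[k], rna_bulge = hits$rna_bulge[k],
          pam_seq = substr(seq, anchors[k] + 1L, anchors[k] + P),
          aligned_spacer = aln[["spacer"]],
          aligned_protospacer = aln[["protospacer"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  .finish_sites(rows)
}

#' @rdname offtarget
#' @details `site_oracle()` refuses chromosomes longer than 10 kb: it exists
#'   to define ground truth at test scale, not to be fast.
#' @export
site_oracle <- function(genome, spacer, rule = "TBN", max_mismatch = 4L,
                        max_bulge = 2L) {
  genome <- .as_genome(genome)
  if (any(nchar(genome) > 10000L))
    stop("site_oracle is restricted to test-scale genomes (<= 10 kb)",
         call. = FALSE)
  spacer <- .check_dna(spacer, "spacer")
  if (nchar(spacer) < 10L) stop("spacer must be at least 10 nt", call. = FALSE)
  if (max_bulge > 2L) stop("bulge budgets above 2 bp are not supported",
                           call. = FALSE)
  sp <- strsplit(spacer, "")[[1]]
  L <- length(sp)
  P <- nchar(rule)
  configs <- .bulge_configs(L, max_bulge)
  rows <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") genome[[chrom]] else .revcomp(genome[[chrom]])
      chars <- strsplit(seq, "")[[1]]
      glen <- length(chars)
      anchors <- .pam_anchors_r(chars, rule)
      if (length(anchors) == 0L) next
      proto0 <- anchors + P
      na <- length(anchors)
      best <- rep(Inf, na); bmm <- bd <- br <- bW <- rep(NA_integer_, na)
      bcf <- rep(NA_integer_, na)
      for (ci in seq_along(configs)) {
        cf <- configs[[ci]]
        valid <- proto0 + cf$W <= glen
        if (!any(valid)) next
        mm <- integer(na)
        for (i in seq_len(L)) {
          if (is.na(cf$offsets[i])) next
          idx <- proto0 + cf$offsets[i] + 1L
          idx[!valid] <- 1L  # placeholder, masked below
          mm <- mm + (chars[idx] != sp[i])
        }
        sc <- .layout_score(mm, cf$d, cf$r, cf$possum)
        sc[!valid | mm > max_mismatch] <- Inf
        upd <- sc < best
        if (any(upd)) {
          best[upd] <- sc[upd]; bmm[upd] <- mm[upd]
          bd[upd] <- cf$d; br[upd] <- cf$r; bW[upd] <- cf$W; bcf[upd] <- ci
        }
      }
      for (k in which(is.finite(best))) {
        p0 <- proto0[k]
        cf <- configs[[bcf[k]]]
        aln <- .render_alignment(chars[(p0 + 1L):(p0 + bW[k])], spacer, cf)
        co <- .strand_coords(p0, bW[k], glen, strand)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = co[1], end = co[2], name = spacer,
          strand = strand, mismatches = bmm[k], dna_bulge = bd[k],
          rna_bulge = br[k],
          pam_seq = paste(chars[(anchors[k] + 1L):(anchors[k] + P)],
                          collapse = ""),
          aligned_spacer = aln[["spacer"]],
          aligned_protospacer = aln[["protospacer"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  .finish_sites(rows)
}

# bind, deduplicate by locus (keep minimal cost), sort
.finish_sites <- function(rows) {
  if (length(rows) == 0L) return(.empty_sites())
  out <- do.call(rbind, rows)
  cost <- out$mismatches + out$dna_bulge + out$rna_bulge
  out <- out[order(out$chrom, out$strand, out$start, out$end, cost), ,
             drop = FALSE]
  key <- paste(out$chrom, out$strand, out$start, out$end)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate sites as BED6+
#'
#' BED columns chrom/start/end/name/score/strand with the mismatch count as
#' score, followed by dna_bulge, rna_bulge, pam_seq and the aligned pair.
#'
#' @param sites data.frame from [find_sites()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$start, sites$end, sites$name,
                    sites$mismatches, sites$strand, sites$dna_bulge,
                    sites$rna_bulge, sites$pam_seq,
                    paste(sites$aligned_spacer, sites$aligned_protospacer,
                          sep = "|"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
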