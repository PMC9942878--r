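#' Default deletion-size distribution for staggered-cut repair
#'
#' Repair of an 8-12 nt 5'-overhang staggered cut yields deletions
#' concentrated at 8-10 bp; this default puts 80% of its mass there, with
#' light tails from 3 to 12 bp (sizes up to 42 bp are supported via custom
#' distributions).
#'
#' @return named numeric vector of probabilities (names are sizes in bp).
#' @export
default_deletion_size_dist <- function() {
  c(`3` = 0.01, `4` = 0.01, `5` = 0.04, `6` = 0.04, `7` = 0.04,
    `8` = 0.30, `9` = 0.30, `10` = 0.20, `11` = 0.03, `12` = 0.03)
}

#' Amplicon simulation configuration
#'
#' Study conditions for the amplicon read simulator: deep sequencing
#' (1e5-1e6 reads per sample) of an amplicon where a small fraction of
#' reads carry a single repair deletion centred near the guide target,
#' contaminated by substitution noise and small (1-2 bp) spurious indels
#' concentrated in homopolymer runs — the error structure the edited-read
#' thresholds were designed against. Noise indels larger than 2 bp are
#' excluded by default; `noise_indel_max_size` is a stress option.
#'
#' @param seed master seed; every generator stage derives its own
#'   substream from it.
#' @param n_reads number of reads to simulate.
#' @param true_efficiency fraction of reads drawn from edited alleles.
#' @param deletion_size_dist named probability vector over deletion sizes
#'   (bp, within 3..42), summing to 1.
#' @param cut_offset deletion midpoint relative to the protospacer 3' end
#'   (bp; negative = PAM-distal end of the protospacer). The paper
#'   constrains the cut chemistry, not the repair-junction coordinate, so
#'   the default -4 keeps deletions inside the protospacer.
#' @param sub_rate per-base substitution probability.
#' @param noise_indel_rate per-read probability of a spurious small indel
#'   at a uniform position.
#' @param homopolymer_slip_rate per-read, per-overlapped-run probability of
#'   an extra 1 bp slip indel inside a homopolymer run (runs >= 6 bp).
#' @param noise_indel_max_size maximum spurious indel size (default 2).
#' @param read_length amplicon length used by [default_amplicon()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 200000L, true_efficiency = 0.011,
                       deletion_size_dist = default_deletion_size_dist(),
                       cut_offset = -4L, sub_rate = 0.001,
                       noise_indel_rate = 0.002,
                       homopolymer_slip_rate = 0.003,
                       noise_indel_max_size = 2L,
                       read_length = 250L) {
  .check_fraction(true_efficiency, "true_efficiency")
  .check_fraction(sub_rate, "sub_rate")
  .check_fraction(noise_indel_rate, "noise_indel_rate")
  .check_fraction(homopolymer_slip_rate, "homopolymer_slip_rate")
  .check_count(n_reads, "n_reads", 1L)
  sizes <- as.integer(names(deletion_size_dist))
  if (anyNA(sizes) || any(sizes < 3L) || any(sizes > 42L))
    stop("deletion sizes must be named integers within 3..42", call. = FALSE)
  if (abs(sum(deletion_size_dist) - 1) > 1e-8)
    stop("deletion_size_dist must sum to 1", call. = FALSE)
  structure(list(seed = .check_count(seed, "seed"),
                 n_reads = as.integer(n_reads),
                 true_efficiency = true_efficiency,
                 deletion_size_dist = deletion_size_dist,
                 cut_offset = as.integer(cut_offset),
                 sub_rate = sub_rate, noise_indel_rate = noise_indel_rate,
                 homopolymer_slip_rate = homopolymer_slip_rate,
                 noise_indel_max_size = as.integer(noise_indel_max_size),
                 read_length = as.integer(read_length)),
            class = "sim_config")
}

#' Default simulated amplicon reference
#'
#' A deterministic `read_length` bp amplicon with the guide protospacer
#' (preceded by a TTC PAM) placed centrally, and one 9 bp adenine run well
#' away from the target so homopolymer masking is exercised.
#'
#' @param cfg a [sim_config()].
#' @param spacer spacer sequence; default a fixed 20-mer.
#' @return an [amplicon_ref()].
#' @export
default_amplicon <- function(cfg = sim_config(),
                             spacer = "GACGTTACAGGCTTCACGAT") {
  len <- cfg$read_length
  base <- .with_substream(20240901L, "amplicon-backbone",
                          sample(c("A", "C", "G", "T"), len, replace = TRUE))
  # avoid accidental homopolymers in the backbone
  for (i in 2:len) if (base[i] == base[i - 1L])
    base[i] <- setdiff(c("A", "C", "G", "T"), base[i - 1L])[1L]
  target_start <- as.integer(len %/% 2 - 10L)
  pam <- c("T", "T", "C")
  base[(target_start - 2L):target_start] <- pam
  base[(target_start + 1L):(target_start + nchar(spacer))] <-
    strsplit(spacer, "")[[1]]
  polyA_at <- 20L
  base[(polyA_at + 1L):(polyA_at + 9L)] <- "A"
  g <- guide_spec("sim-guide", spacer, pam_rule = "TBN",
                  target_chrom = "amplicon", target_start = target_start,
                  target_end = target_start + nchar(spacer),
                  target_strand = "+")
  amplicon_ref("amplicon", paste(base, collapse = ""), g)
}

#' Simulate edited alleles by staggered-cut deletion
#'
#' Draws `n` deletion sizes from the configured distribution and removes,
#' for each, the window whose midpoint sits at the protospacer 3' end plus
#' `cut_offset`. The planted event is recorded in reference coordinates
#' after left-normalization, so truth labels and recovered pattern keys are
#' directly comparable.
#'
#' @param ref an [amplicon_ref()] (supplies sequence and guide).
#' @param cfg a [sim_config()].
#' @param n number of alleles to draw.
#' @return list of `n` entries, each `list(seq, event)` where `event` is a
#'   one-row left-normalized indel data.frame with a `key` column.
#' @export
simulate_edit_alleles <- function(ref, cfg, n) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(cfg, "sim_config"))
  n <- .check_count(n, "n")
  if (n == 0L) return(list())
  g <- ref$guide
  if (is.na(g$target_start))
    stop("guide has no target coordinates on this amplicon", call. = FALSE)
  sizes <- as.integer(names(cfg$deletion_size_dist))
  maxsize <- max(sizes)
  cut3 <- if (g$target_strand == "+") g$target_end else g$target_start
  mid <- cut3 + cfg$cut_offset
  reflen <- nchar(ref$sequence)
  if (mid - maxsize < 0L || mid + maxsize > reflen)
    stop("guide target too close to the amplicon edge for the configured ",
         "deletion sizes (need ", maxsize, " bp of flank)", call. = FALSE)
  refchars <- strsplit(ref$sequence, "")[[1]]
  drawn <- .with_substream(cfg$seed, "alleles",
                           sizes[sample.int(length(sizes), n, replace = TRUE,
                                            prob = cfg$deletion_size_dist)])
  lapply(drawn, function(size) {
    start <- mid - size %/% 2L
    nm <- .normalize_deletion(refchars, start, size)
    seq <- paste0(substr(ref$sequence, 1L, nm$start),
                  substr(ref$sequence, nm$start + size + 1L, reflen))
    event <- data.frame(kind = "deletion", start = nm$start, size = size,
                        seq = nm$seq, ambiguity_end = nm$ambiguity_end,
                        key = paste("deletion", size, nm$start, sep = ":"),
                        stringsAsFactors = FALSE)
    list(seq = seq, event = event)
  })
}

# apply substitutions then small indels to one read string
.mutate_read <- function(seq, sub_pos, sub_base, indels) {
  ch <- strsplit(seq, "")[[1]]
  if (length(sub_pos)) {
    for (k in seq_along(sub_pos)) {
      p <- sub_pos[k]
      alt <- setdiff(c("A", "C", "G", "T"), ch[p])
      ch[p] <- alt[sub_base[k]]
    }
  }
  if (!is.null(indels) && nrow(indels)) {
    for (k in seq_len(nrow(indels))) {
      p <- min(indels$pos[k], length(ch))
      sz <- indels$size[k]
      if (indels$kind[k] == "deletion") {
        ch <- ch[-(p:min(p + sz - 1L, length(ch)))]
      } else {
        ins <- sample(c("A", "C", "G", "T"), sz, replace = TRUE)
        ch <- append(ch, ins, after = p)
      }
    }
  }
  paste(ch, collapse = "")
}

#' Simulate an amplicon read set with truth labels
#'
#' Each read is drawn from an edited allele with probability
#' `cfg$true_efficiency` (uniformly over `alleles`), otherwise from the
#' reference; substitution noise, spurious 1-2 bp indels and homopolymer
#' slippage are then applied. Fixed seed gives byte-identical output.
#'
#' @param ref an [amplicon_ref()].
#' @param alleles output of [simulate_edit_alleles()]; may be empty only if
#'   `true_efficiency` is 0.
#' @param cfg a [sim_config()].
#' @return list of class `amplicon_sim`: `reads` (character vector),
#'   `truth` (data.frame `read`, `label`, `pattern_key`), `ref`, `cfg`.
#' @export
simulate_amplicon_reads <- function(ref, alleles, cfg) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(cfg, "sim_config"))
  n <- cfg$n_reads
  if (cfg$true_efficiency > 0 && length(alleles) == 0L)
    stop("true_efficiency > 0 requires at least one edited allele",
         call. = FALSE)
  .with_substream(cfg$seed, "reads", {
    edited <- runif(n) < cfg$true_efficiency
    allele_idx <- integer(n)
    if (any(edited))
      allele_idx[edited] <- sample.int(length(alleles), sum(edited),
                                       replace = TRUE)
    allele_seqs <- vapply(alleles, `[[`, character(1), "seq")
    allele_keys <- vapply(alleles, function(a) a$event$key, character(1))
    base <- rep(ref$sequence, n)
    if (any(edited)) base[edited] <- allele_seqs[allele_idx[edited]]
    lens <- nchar(base)

    # substitution noise
    nsub <- rbinom(n, lens, cfg$sub_rate)
    # spurious small indels at uniform positions
    has_noise <- runif(n) < cfg$noise_indel_rate
    # homopolymer slippage: per overlapped run (runs >= 6 bp on the reference)
    runs <- detect_homopolymer_masks(ref$sequence, min_run = 6L)
    nslip <- if (nrow(runs)) rbinom(n, nrow(runs), cfg$homopolymer_slip_rate)
             else integer(n)

    touched <- which(nsub > 0L | has_noise | nslip > 0L)
    reads <- base
    for (i in touched) {
      sub_pos <- if (nsub[i] > 0L) sample.int(lens[i], nsub[i]) else integer()
      sub_base <- if (nsub[i] > 0L) sample.int(3L, nsub[i], replace = TRUE)
                  else integer()
      ind <- NULL
      if (has_noise[i]) {
        ind <- data.frame(
          kind = sample(c("deletion", "insertion"), 1L),
          pos = sample.int(lens[i] - cfg$noise_indel_max_size, 1L),
          size = sample.int(cfg$noise_indel_max_size, 1L))
      }
      if (nslip[i] > 0L) {
        ri <- sample.int(nrow(runs), nslip[i])
        slip <- data.frame(
          kind = sample(c("deletion", "insertion"), nslip[i], replace = TRUE),
          pos = runs[ri, 1L] + 1L,  # inside the run (ref coords, ~read coords)
          size = 1L)
        ind <- if (is.null(ind)) slip else rbind(ind, slip)
      }
      reads[i] <- .mutate_read(base[i], sub_pos, sub_base, ind)
    }
    pattern_key <- rep(NA_character_, n)
    if (any(edited)) pattern_key[edited] <- allele_keys[allele_idx[edited]]
    truth <- data.frame(
      read = seq_len(n),
      label = ifelse(edited, "edited", "unedited"),
      pattern_key = pattern_key,
      stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth, ref = ref, cfg = cfg),
              class = "amplicon_sim")
  })
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf("simulated amplicon run: %s reads, %s edited (%.3f%%)\n",
              format(length(x$reads), big.mark = ","),
              format(sum(x$truth$label == "edited"), big.mark = ","),
              100 * mean(x$truth$label == "edited")))
  invisible(x)
}
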