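#' WGS call-set simulation configuration
#'
#' Study conditions for the whole-genome screening stage: two caller call
#' sets from an edited plant plus one background-line call set over a toy
#' genome. Shared background variants appear in all three sets; spontaneous
#' private mutations and planted heterozygous edits appear in both caller
#' sets only. Artifact classes exercise each cascade stage: caller-private
#' calls (removed by the two-caller intersection), shared calls with
#' failing annotations (removed by the hard filters), low-allele-fraction
#' and low-coverage calls (removed by the depth/allele-balance filter), and
#' calls inside simple repeats (removed by the repeat filter).
#'
#' The annotation model draws true calls to pass all hard filters with
#' >= 99% probability (QD ~ N(25, 4), FS ~ Exp(mean 3), MQ ~ N(60, 1.5),
#' SOR ~ Exp(mean 0.6)) and artifact calls to fail at least one with
#' probability `artifact_fail_prob` (one annotation redrawn from a failing
#' range).
#'
#' @param seed master seed.
#' @param genome_length length of each toy chromosome (bp).
#' @param n_chrom number of toy chromosomes.
#' @param background_variant_rate shared background variants per bp.
#' @param private_mutation_count spontaneous mutations private to the
#'   edited sample.
#' @param planted_edits data.frame with `chrom`, `pos`, and optionally
#'   `allele_fraction` (default 0.5): heterozygous edits to plant at
#'   predicted off-target loci. `NULL` for none.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param n_caller_private artifact calls private to each caller.
#' @param n_shared_artifact shared calls with failing annotations.
#' @param n_low_af shared calls at low allele fraction (0.05-0.15).
#' @param n_low_cov shared calls at ~1/4 of `mean_depth`.
#' @param n_repeat_artifact shared 1 bp indels inside simple repeats.
#' @param artifact_fail_prob probability an artifact call gets a failing
#'   annotation (default 1: artifacts always carry one; values below 1 are
#'   a stress option that lets annotation-clean artifacts through, as real
#'   data does).
#' @return list of class `wgs_sim_config`.
#' @export
wgs_sim_config <- function(seed = 1L, genome_length = 50000L, n_chrom = 2L,
                           background_variant_rate = 5e-4,
                           private_mutation_count = 5L, planted_edits = NULL,
                           mean_depth = 60, n_caller_private = 6L,
                           n_shared_artifact = 5L, n_low_af = 4L,
                           n_low_cov = 3L, n_repeat_artifact = 5L,
                           artifact_fail_prob = 1) {
  .check_fraction(artifact_fail_prob, "artifact_fail_prob")
  if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  if (!is.null(planted_edits)) {
    stopifnot(is.data.frame(planted_edits),
              all(c("chrom", "pos") %in% names(planted_edits)))
    if (is.null(planted_edits$allele_fraction))
      planted_edits$allele_fraction <- 0.5
    af <- planted_edits$allele_fraction
    if (any(af <= 0 | af > 1))
      stop("allele_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(seed = .check_count(seed, "seed"),
                 genome_length = .check_count(genome_length, "genome_length", 1000L),
                 n_chrom = .check_count(n_chrom, "n_chrom", 1L),
                 background_variant_rate = background_variant_rate,
                 private_mutation_count = .check_count(private_mutation_count,
                                                       "private_mutation_count"),
                 planted_edits = planted_edits, mean_depth = mean_depth,
                 n_caller_private = .check_count(n_caller_private, "n_caller_private"),
                 n_shared_artifact = .check_count(n_shared_artifact, "n_shared_artifact"),
                 n_low_af = .check_count(n_low_af, "n_low_af"),
                 n_low_cov = .check_count(n_low_cov, "n_low_cov"),
                 n_repeat_artifact = .check_count(n_repeat_artifact, "n_repeat_artifact"),
                 artifact_fail_prob = artifact_fail_prob),
            class = "wgs_sim_config")
}

#' Simulate a toy genome with embedded simple repeats
#'
#' Random chromosomes with a mononucleotide run (12-15 bp) and a
#' dinucleotide tandem (7 units) inserted every ~5 kb, so the repeat
#' filter always has real context to act on.
#'
#' @param cfg a [wgs_sim_config()].
#' @return named character vector of chromosome sequences.
#' @export
simulate_toy_genome <- function(cfg) {
  stopifnot(inherits(cfg, "wgs_sim_config"))
  .with_substream(cfg$seed, "genome", {
    out <- character(cfg$n_chrom)
    names(out) <- paste0("chr", seq_len(cfg$n_chrom))
    for (ci in seq_len(cfg$n_chrom)) {
      chars <- sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)
      at <- seq(2500L, cfg$genome_length - 100L, by = 5000L)
      for (p in at) {
        b <- sample(c("A", "C", "G", "T"), 1L)
        run <- sample(12:15, 1L)
        chars[p:(p + run - 1L)] <- b
        unit <- sample(c("AT", "TA", "AC", "GT", "AG", "CT"), 1L)
        du <- strsplit(unit, "")[[1]]
        q <- p + 40L
        chars[q:(q + 13L)] <- rep(du, 7L)
      }
      out[ci] <- paste(chars, collapse = "")
    }
    out
  })
}

# annotation draws
.true_annotations <- function(n) {
  data.frame(qd = rnorm(n, 25, 4), fs = rexp(n, 1 / 3),
             mq = rnorm(n, 60, 1.5), sor = stats::rgamma(n, shape = 2, rate = 4))
}

.artifact_annotations <- function(n, vtype, fail_prob) {
  ann <- .true_annotations(n)
  for (i in seq_len(n)) {
    if (runif(1) >= fail_prob) next
    which_ann <- if (vtype[i] == "SNP") sample(c("qd", "fs", "mq", "sor"), 1L)
                 else sample(c("qd", "fs", "sor"), 1L)
    ann[i, which_ann] <- switch(
      which_ann,
      qd = runif(1, 0, 1.9),
      fs = if (vtype[i] == "SNP") runif(1, 70, 300) else runif(1, 210, 400),
      mq = runif(1, 20, 39),
      sor = if (vtype[i] == "SNP") runif(1, 4.5, 9) else runif(1, 10.5, 15))
  }
  ann
}

# build variant rows at given loci
.make_variants <- function(genome, chrom, pos, vtype, af, depth, ann, caller) {
  n <- length(pos)
  if (n == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), ad_ref = integer(),
                      ad_alt = integer(), dp = integer(), qd = numeric(),
                      fs = numeric(), mq = numeric(), sor = numeric(),
                      caller = character(), stringsAsFactors = FALSE))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    chars <- strsplit(substr(genome[[chrom[i]]], pos[i], pos[i] + 4L), "")[[1]]
    if (vtype[i] == "SNP") {
      ref[i] <- chars[1]
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[1]), 1L)
    } else if (runif(1) < 0.5) {  # short deletion
      k <- sample(1:2, 1L)
      ref[i] <- paste(chars[1:(k + 1L)], collapse = "")
      alt[i] <- chars[1]
    } else {                      # short insertion
      ref[i] <- chars[1]
      alt[i] <- paste0(chars[1], paste(sample(c("A", "C", "G", "T"),
                                              sample(1:2, 1L), replace = TRUE),
                                       collapse = ""))
    }
  }
  dp <- pmax(1L, rpois(n, depth))
  ad_alt <- rbinom(n, dp, af)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             ad_ref = dp - ad_alt, ad_alt = ad_alt, dp = dp,
             qd = ann$qd, fs = ann$fs, mq = ann$mq, sor = ann$sor,
             caller = caller, stringsAsFactors = FALSE)
}

#' Simulate paired whole-genome call sets with truth labels
#'
#' Generates a toy genome (unless given), then three call sets: caller A
#' (with annotations), caller B (same shared calls, annotations absent, as
#' from a second caller), and the background line. Planted heterozygous
#' edits draw allele fractions near 0.5 at the configured depth. Planted
#' loci never collide with other simulated loci (candidate positions are
#' excluded deterministically per seed).
#'
#' @param cfg a [wgs_sim_config()].
#' @param genome optional pre-built genome (named character vector); by
#'   default [simulate_toy_genome()] is used.
#' @return list of class `wgs_sim`: `a`, `b`, `background` (data.frames),
#'   `truth` (data.frame `key`, `label`), `genome`.
#' @export
simulate_wgs_callsets <- function(cfg, genome = NULL) {
  stopifnot(inherits(cfg, "wgs_sim_config"))
  if (is.null(genome)) genome <- simulate_toy_genome(cfg)
  .with_substream(cfg$seed, "callsets", {
    # repeat intervals per chromosome (1-based position pool bookkeeping)
    repiv <- lapply(genome, .repeat_intervals, mono_min = 10L, di_min = 6L)
    planted <- cfg$planted_edits
    reserved <- if (!is.null(planted))
      paste(planted$chrom, planted$pos) else character()

    draw_loci <- function(n, in_repeat = FALSE) {
      # deterministic rejection sampling: collisions with reserved loci and
      # wrong repeat context are redrawn, so planted loci never collide
      if (n == 0L) return(data.frame(chrom = character(), pos = integer()))
      rows <- list()
      guard <- 0L
      while (length(rows) < n && guard < 10000L) {
        guard <- guard + 1L
        chrom <- sample(names(genome), 1L)
        iv <- repiv[[chrom]]
        if (in_repeat) {
          if (nrow(iv) == 0L) next
          k <- sample.int(nrow(iv), 1L)
          lo <- iv[k, 1] + 2L; hi <- iv[k, 2] - 2L  # 1-based anchor inside run
          if (hi < lo) next
          pos <- if (hi == lo) lo else sample(lo:hi, 1L)
        } else {
          pos <- sample.int(cfg$genome_length - 50L, 1L) + 10L
          near <- nrow(iv) > 0L &&
            any(iv[, 1] - 5L <= pos & pos <= iv[, 2] + 5L)
          if (near) next  # keep true variants clear of repeat context
        }
        key <- paste(chrom, pos)
        if (key %in% reserved) next
        reserved <<- c(reserved, key)
        rows[[length(rows) + 1L]] <- data.frame(chrom = chrom, pos = pos,
                                                stringsAsFactors = FALSE)
      }
      if (length(rows) < n)
        stop("could not place ", n, " simulated loci", call. = FALSE)
      do.call(rbind, rows)
    }

    n_bg <- rbinom(1L, cfg$genome_length * cfg$n_chrom,
                   cfg$background_variant_rate)
    bg <- draw_loci(n_bg)
    priv <- draw_loci(cfg$private_mutation_count)
    shared_art <- draw_loci(cfg$n_shared_artifact)
    low_af <- draw_loci(cfg$n_low_af)
    low_cov <- draw_loci(cfg$n_low_cov)
    rep_art <- draw_loci(cfg$n_repeat_artifact, in_repeat = TRUE)
    a_priv <- draw_loci(cfg$n_caller_private)
    b_priv <- draw_loci(cfg$n_caller_private)

    vt <- function(df, p_snp = 0.8)
      sample(c("SNP", "indel"), nrow(df), replace = TRUE,
             prob = c(p_snp, 1 - p_snp))
    zyg <- function(df) sample(c(0.5, 1), nrow(df), replace = TRUE)

    bg_vt <- vt(bg); bg_af <- zyg(bg)
    bg_rows <- .make_variants(genome, bg$chrom, bg$pos, bg_vt, bg_af,
                              cfg$mean_depth, .true_annotations(nrow(bg)), "gatk")
    priv_vt <- vt(priv)
    priv_rows <- .make_variants(genome, priv$chrom, priv$pos, priv_vt,
                                zyg(priv), cfg$mean_depth,
                                .true_annotations(nrow(priv)), "gatk")
    plant_rows <- NULL
    if (!is.null(planted) && nrow(planted)) {
      pl_vt <- rep("SNP", nrow(planted))
      plant_rows <- .make_variants(genome, planted$chrom, planted$pos, pl_vt,
                                   planted$allele_fraction, cfg$mean_depth,
                                   .true_annotations(nrow(planted)), "gatk")
    }
    sa_vt <- vt(shared_art, 0.5)
    sa_rows <- .make_variants(genome, shared_art$chrom, shared_art$pos, sa_vt,
                              zyg(shared_art), cfg$mean_depth,
                              .artifact_annotations(nrow(shared_art), sa_vt,
                                                    cfg$artifact_fail_prob),
                              "gatk")
    la_vt <- vt(low_af)
    la_rows <- .make_variants(genome, low_af$chrom, low_af$pos, la_vt,
                              runif(nrow(low_af), 0.02, 0.06), cfg$mean_depth,
                              .true_annotations(nrow(low_af)), "gatk")
    lc_vt <- vt(low_cov)
    lc_rows <- .make_variants(genome, low_cov$chrom, low_cov$pos, lc_vt,
                              zyg(low_cov), cfg$mean_depth / 6,
                              .true_annotations(nrow(low_cov)), "gatk")
    ra_rows <- .make_variants(genome, rep_art$chrom, rep_art$pos,
                              rep("indel", nrow(rep_art)), zyg(rep_art),
                              cfg$mean_depth,
                              .true_annotations(nrow(rep_art)), "gatk")
    # repeat artifacts are 1 bp slippage deletions of a run base, the
    # signature the repeat filter is meant to catch
    for (i in seq_len(nrow(ra_rows))) {
      g <- genome[[ra_rows$chrom[i]]]
      ra_rows$ref[i] <- substr(g, ra_rows$pos[i], ra_rows$pos[i] + 1L)
      ra_rows$alt[i] <- substr(g, ra_rows$pos[i], ra_rows$pos[i])
    }
    ap_vt <- vt(a_priv)
    ap_rows <- .make_variants(genome, a_priv$chrom, a_priv$pos, ap_vt,
                              zyg(a_priv), cfg$mean_depth,
                              .true_annotations(nrow(a_priv)), "gatk")
    bp_vt <- vt(b_priv)
    bp_rows <- .make_variants(genome, b_priv$chrom, b_priv$pos, bp_vt,
                              zyg(b_priv), cfg$mean_depth,
                              .true_annotations(nrow(b_priv)), "strelka")

    shared <- rbind(bg_rows, priv_rows, plant_rows, sa_rows, la_rows,
                    lc_rows, ra_rows)
    a <- rbind(shared, ap_rows)
    b <- rbind(shared, bp_rows)
    b$caller <- "strelka"
    b$qd <- b$fs <- b$mq <- b$sor <- NA_real_  # second caller: no annotations
    background <- bg_rows

    lab <- function(rows, label) if (is.null(rows) || nrow(rows) == 0L)
      NULL else data.frame(key = .variant_key(rows), label = label,
                           stringsAsFactors = FALSE)
    truth <- rbind(lab(bg_rows, "background"), lab(priv_rows, "private"),
                   lab(plant_rows, "planted"),
                   lab(sa_rows, "artifact_annotation"),
                   lab(la_rows, "artifact_low_af"),
                   lab(lc_rows, "artifact_low_cov"),
                   lab(ra_rows, "artifact_repeat"),
                   lab(ap_rows, "artifact_caller_A"),
                   lab(bp_rows, "artifact_caller_B"))
    structure(list(a = a, b = b, background = background, truth = truth,
                   genome = genome), class = "wgs_sim")
  })
}

#' @export
print.wgs_sim <- function(x, ...) {
  cat(sprintf("simulated WGS call sets: %d (A), %d (B), %d background\n",
              nrow(x$a), nrow(x$b), nrow(x$background)))
  print(table(x$truth$label))
  invisible(x)
}
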