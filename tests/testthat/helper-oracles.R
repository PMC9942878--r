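# Independent oracles and fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive affine-gap global alignment score, straight three-matrix
# dynamic program in R. Independent of the package's aligner; used to
# check scores on short references.
oracle_align_score <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = 10, gap_ext = 1) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) X[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) Y[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             X[i + 1, j] - gap_ext,
                             Y[i + 1, j] - gap_open - gap_ext)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_open - gap_ext,
                             Y[i, j + 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive binomial summation: probability that with n reads at allele
# fraction 1/2 the reference/variant ratio exceeds the cutoff.
oracle_ratio_tail <- function(n, cutoff = 3) {
  ks <- 0:n
  drop <- (n - ks) > cutoff * ks
  sum(choose(n, ks)[drop]) / 2^n
}

# A small amplicon fixture with a guide and a poly-A run.
fixture_amplicon <- function(read_length = 200L, seed = 5L) {
  cfg <- sim_config(seed = seed, n_reads = 10L, read_length = read_length)
  default_amplicon(cfg)
}

# Random genome with an embedded perfect protospacer (TTC PAM) for the
# off-target search tests.
fixture_genome_with_site <- function(len = 2000L, spacer, at = 500L,
                                     name = "chrA") {
  gs <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  gs[at:(at + 2L)] <- c("T", "T", "C")
  gs[(at + 3L):(at + 2L + nchar(spacer))] <- strsplit(spacer, "")[[1]]
  setNames(paste(gs, collapse = ""), name)
}

site_identity <- function(sites) {
  cols <- c("chrom", "start", "end", "strand", "mismatches", "dna_bulge",
            "rna_bulge", "pam_seq")
  sort(do.call(paste, sites[cols]))
}

# Minimal variant record data.frame builder.
vrec <- function(chrom = "chr1", pos, ref = "A", alt = "G", ad_ref = 30L,
                 ad_alt = 30L, dp = NA_integer_, qd = 20, fs = 1, mq = 60,
                 sor = 1, caller = "gatk") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, qd = qd, fs = fs,
             mq = mq, sor = sor, caller = caller, stringsAsFactors = FALSE)
}
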