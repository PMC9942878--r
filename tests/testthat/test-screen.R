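test_that("multiallelic records split with per-allele depths", {
  raw <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G,T",
                    ad_ref = 30L, ad_alt = "10,12", dp = 52L,
                    stringsAsFactors = FALSE)
  x <- split_and_key(raw)
  expect_identical(nrow(x), 2L)
  expect_identical(x$alt, c("G", "T"))
  expect_identical(x$ad_alt, c(10L, 12L))
  expect_identical(unique(x$ref), "A")
  # biallelic input passes through; duplicates collapse
  y <- split_and_key(rbind(vrec(pos = 5), vrec(pos = 5)))
  expect_identical(nrow(y), 1L)
  # malformed ref/alt rejected with a reason
  z <- split_and_key(data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                alt = "A", stringsAsFactors = FALSE))
  expect_identical(nrow(z), 0L)
  expect_identical(attr(z, "rejected")$reason, "malformed ref/alt")
})

test_that("caller intersection keys on (chrom, pos, ref, alt)", {
  a <- split_and_key(rbind(vrec(pos = 10), vrec(pos = 20, alt = "T"),
                           vrec(pos = 30)))
  b <- split_and_key(rbind(vrec(pos = 10), vrec(pos = 20, alt = "C"),
                           vrec(pos = 40)))
  x <- intersect_callsets(a, b)
  expect_identical(x$pos, 10L)  # same locus, different alt is excluded
  expect_identical(nrow(intersect_callsets(a, a)), nrow(a))
  expect_identical(nrow(intersect_callsets(
    a, split_and_key(vrec(pos = 99)))), 0L)
})

test_that("hard filters apply per variant type and tolerate missing values", {
  cfg <- screen_config()
  keep <- function(x) nrow(apply_hard_filters(split_and_key(x), cfg))
  expect_identical(keep(vrec(pos = 1, qd = 1.5)), 0L)             # QD < 2
  expect_identical(keep(vrec(pos = 1, fs = 61)), 0L)              # FS > 60
  expect_identical(keep(vrec(pos = 1, mq = 39)), 0L)              # MQ < 40
  expect_identical(keep(vrec(pos = 1, sor = 4.5)), 0L)            # SOR > 4
  expect_identical(keep(vrec(pos = 1, qd = 10, fs = 5, mq = 60, sor = 1)), 1L)
  # indel thresholds are looser: FS 100 passes an indel, fails a SNP
  expect_identical(keep(vrec(pos = 1, ref = "AT", alt = "A", fs = 100)), 1L)
  expect_identical(keep(vrec(pos = 1, fs = 100)), 0L)
  expect_identical(keep(vrec(pos = 1, ref = "AT", alt = "A", fs = 250)), 0L)
  expect_identical(keep(vrec(pos = 1, ref = "AT", alt = "A", sor = 5)), 1L)
  # MQ never applies to indels; missing annotations pass
  expect_identical(keep(vrec(pos = 1, ref = "AT", alt = "A", mq = 20)), 1L)
  expect_identical(keep(vrec(pos = 1, qd = NA, fs = NA, mq = NA, sor = NA)), 1L)
})

test_that("background subtraction removes identical calls only", {
  recs <- split_and_key(rbind(vrec(pos = 10), vrec(pos = 20)))
  bg <- split_and_key(vrec(pos = 10))
  out <- subtract_background(recs, bg)
  expect_identical(out$pos, 20L)
  # same position, different alt is retained
  bg2 <- split_and_key(vrec(pos = 20, alt = "T"))
  expect_identical(nrow(subtract_background(recs, bg2)), 2L)
  # background superset empties the sample
  expect_identical(nrow(subtract_background(recs, recs)), 0L)
  expect_warning(subtract_background(recs, split_and_key(vrec(pos = 1)[0, ])),
                 "empty background")
})

test_that("coverage and allele-balance rules are strict as written", {
  cfg <- screen_config()
  keep <- function(x) nrow(depth_and_ratio_filter(split_and_key(x), cfg))
  expect_identical(keep(vrec(pos = 1, ad_ref = 100, ad_alt = 20)), 0L) # 5 > 3
  expect_identical(keep(vrec(pos = 1, ad_ref = 40, ad_alt = 40)), 1L)
  expect_identical(keep(vrec(pos = 1, ad_ref = 20, ad_alt = 5)), 0L)   # 25 < 30
  expect_identical(keep(vrec(pos = 1, ad_ref = 90, ad_alt = 30)), 1L)  # ratio 3
  expect_identical(keep(vrec(pos = 1, ad_ref = 22, ad_alt = 8)), 1L)   # cov 30
  expect_identical(keep(vrec(pos = 1, ad_ref = 30, ad_alt = 0)), 0L)   # no alt
  # AD missing: DP backs up coverage, ratio cannot fail
  expect_identical(keep(vrec(pos = 1, ad_ref = NA, ad_alt = NA, dp = 50L)), 1L)
  expect_identical(keep(vrec(pos = 1, ad_ref = NA, ad_alt = NA, dp = 20L)), 0L)
  x <- depth_and_ratio_filter(split_and_key(
    vrec(pos = 1, ad_ref = NA, ad_alt = NA, dp = NA_integer_)), cfg)
  expect_identical(nrow(x), 0L)
  expect_identical(attr(x, "rejected")$reason, "no AD or DP")
})

test_that("heterozygote miss probability equals the summation oracle", {
  for (n in 1:64)
    expect_equal(het_detection_power(n, 3), oracle_ratio_tail(n, 3))
  expect_equal(round(het_detection_power(30, 3), 4), 0.0026)
  # n = 20: explicit closed form from the binomial tail
  expect_equal(het_detection_power(20, 3), sum(choose(20, 0:4)) / 2^20)
  # vanishes with coverage: compare over one threshold period
  n4 <- seq(12, 200, by = 4)
  expect_true(all(diff(het_detection_power(n4, 3)) < 0))
  expect_lt(het_detection_power(200, 3), het_detection_power(10, 3))
  # a more tolerant ratio cutoff discards fewer true heterozygotes
  expect_gt(het_detection_power(30, 2), het_detection_power(30, 3))
  expect_gt(het_detection_power(30, 3), het_detection_power(30, 5))
  expect_equal(het_detection_power(30, 2), oracle_ratio_tail(30, 2))
  expect_equal(het_detection_power(30, 5), oracle_ratio_tail(30, 5))
})

test_that("repeat filter removes only variants confined to simple repeats", {
  # period-3 flanks are neither mono- nor di-nucleotide repeats:
  # A-run at 1-based 41..52, GT tandem at 93..108
  g <- c(chr1 = paste0(strrep("GAC", 13), "G", strrep("A", 12),
                       strrep("GAC", 13), "G", strrep("GT", 8),
                       strrep("CAG", 13), "C"))
  cfg <- screen_config(repeat_mono_min = 10, repeat_di_min = 6)
  chars <- strsplit(g[[1]], "")[[1]]
  # 1 bp deletion inside the 12xA run (run occupies 1-based 41..52)
  delA <- vrec(pos = 42, ref = paste0(chars[42], chars[43]), alt = chars[42])
  expect_identical(nrow(simple_repeat_filter(split_and_key(delA), g, cfg)), 0L)
  # SNP in the A-run: single position inside the run
  snpA <- vrec(pos = 45, ref = "A", alt = "G")
  expect_identical(nrow(simple_repeat_filter(split_and_key(snpA), g, cfg)), 0L)
  # SNP in unique context is kept
  snpU <- vrec(pos = 20, ref = chars[20], alt = "T")
  expect_identical(nrow(simple_repeat_filter(split_and_key(snpU), g, cfg)), 1L)
  # deletion spanning the run boundary is kept (containment rule)
  delB <- vrec(pos = 38, ref = paste(chars[38:44], collapse = ""),
               alt = chars[38])
  expect_identical(nrow(simple_repeat_filter(split_and_key(delB), g, cfg)), 1L)
  # 1 bp deletion in the GT tandem (1-based 93..108) is removed
  delGT <- vrec(pos = 95, ref = paste0(chars[95], chars[96]), alt = chars[95])
  expect_identical(nrow(simple_repeat_filter(split_and_key(delGT), g, cfg)), 0L)
  # variant outside the genome errors
  expect_error(simple_repeat_filter(split_and_key(vrec(pos = 10000L)), g, cfg),
               "outside")
})

test_that("off-target overlap annotation uses padded site spans", {
  sites <- data.frame(chrom = "chr1", start = 100L, end = 120L, name = "sp",
                      strand = "+", mismatches = 2L, dna_bulge = 0L,
                      rna_bulge = 0L, pam_seq = "TTC",
                      aligned_spacer = "", aligned_protospacer = "",
                      stringsAsFactors = FALSE)
  inside <- split_and_key(vrec(pos = 110))
  near <- split_and_key(vrec(pos = 135))    # within the 20 bp pad
  far <- split_and_key(vrec(pos = 160))
  expect_identical(annotate_offtarget_overlap(inside, sites)$n_overlap, 1L)
  expect_identical(annotate_offtarget_overlap(near, sites)$n_overlap, 1L)
  expect_identical(annotate_offtarget_overlap(far, sites)$n_overlap, 0L)
  expect_identical(annotate_offtarget_overlap(inside, sites[0, ])$n_overlap, 0L)
})

test_that("intersection and background subtraction commute", {
  set.seed(301)
  mk <- function(n) split_and_key(vrec(pos = sample(1000, n),
                                       alt = sample(c("G", "T"), n, TRUE)))
  for (k in 1:5) {
    a <- mk(30); b <- mk(30); bg <- mk(15)
    x1 <- subtract_background(intersect_callsets(a, b), bg)
    x2 <- intersect_callsets(subtract_background(a, bg),
                             subtract_background(b, bg))
    expect_identical(sort(x1$key), sort(x2$key))
  }
})

test_that("the cascade is monotone and orders stages as designed", {
  cfg <- wgs_sim_config(seed = 33L)
  sim <- simulate_wgs_callsets(cfg)
  rep <- screen_variants(sim$a, sim$b, sim$background, sim$genome)
  n <- rep$stages$n
  stage_from_intersection <- n[-(1:2)]
  expect_true(all(diff(stage_from_intersection) <= 0))
  expect_identical(rep$stages$stage[3], "intersection")
  expect_identical(sum(rep$summary), nrow(rep$variants))
})
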