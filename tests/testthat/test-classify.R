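del_event <- function(start, size, amb = start) data.frame(
  kind = "deletion", start = start, size = size, seq = strrep("A", size),
  ambiguity_end = amb, stringsAsFactors = FALSE)

table_of <- function(...) {
  # build a pattern table from (event, n_reads) pairs plus clean reads
  specs <- list(...)
  evs <- list()
  for (s in specs) evs <- c(evs, rep(list(s$ev), s$n))
  build_pattern_table(evs, n_total = sum(vapply(specs, `[[`, 1, "n")) + 1000L)
}

test_that("classification enforces size, count and mask criteria", {
  cfg <- edit_call_config(min_indel_size = 3, min_pattern_reads = 100)
  # abundant 2 bp deletion: excluded for size, however many reads
  t1 <- table_of(list(ev = del_event(40, 2), n = 500))
  r1 <- classify_edited(t1, cfg)
  expect_identical(r1$edited_reads, 0L)
  expect_match(r1$excluded_patterns$reason, "min_size")
  # 9 bp deletion one read short of the threshold: excluded for count
  t2 <- table_of(list(ev = del_event(40, 9), n = 99))
  r2 <- classify_edited(t2, cfg)
  expect_identical(r2$edited_reads, 0L)
  expect_match(r2$excluded_patterns$reason, "min_count")
  expect_identical(classify_edited(
    table_of(list(ev = del_event(40, 9), n = 100)), cfg)$edited_reads, 100L)
  # 4 bp deletion confined to a masked poly-A run: excluded by the mask
  masks <- matrix(c(30L, 50L), 1)
  t3 <- table_of(list(ev = del_event(38, 4, amb = 42), n = 300))
  r3 <- classify_edited(t3, cfg, masks)
  expect_identical(r3$edited_reads, 0L)
  expect_match(r3$excluded_patterns$reason, "mask")
  # partial overlap with the mask does not mask
  t4 <- table_of(list(ev = del_event(28, 4, amb = 28), n = 300))
  expect_identical(classify_edited(t4, cfg, masks)$edited_reads, 300L)
})

test_that("a read with several qualifying patterns is counted once", {
  cfg <- edit_call_config(min_pattern_reads = 2)
  two <- rbind(del_event(10, 5), del_event(40, 9))
  tab <- build_pattern_table(rep(list(two), 3), n_total = 10L)
  res <- classify_edited(tab, cfg)
  expect_identical(nrow(res$qualifying_patterns), 2L)
  expect_identical(res$edited_reads, 3L)
})

test_that("an empty table warns and reports zero efficiency", {
  tab <- build_pattern_table(list(), n_total = 0L)
  expect_warning(res <- classify_edited(tab), "empty")
  expect_identical(res$efficiency, 0)
})

test_that("efficiency arithmetic follows the 2-significant-figure rule", {
  e1 <- editing_efficiency(79768, 9404589)
  expect_identical(e1$percent, 0.85)
  expect_equal(e1$fraction, 79768 / 9404589)
  expect_identical(editing_efficiency(91950, 8572470)$percent, 1.1)
  expect_identical(editing_efficiency(0, 1000)$percent, 0)
  expect_error(editing_efficiency(1, 0), "positive")
  expect_error(editing_efficiency(5, 4))
})

test_that("raising thresholds or adding masks never adds edited reads", {
  set.seed(105)
  for (k in 1:10) {
    n_pat <- sample(3:8, 1)
    evs <- lapply(seq_len(n_pat), function(i)
      del_event(sample(10:150, 1), sample(1:12, 1)))
    counts <- sample(1:300, n_pat, replace = TRUE)
    all_evs <- list()
    for (i in seq_len(n_pat)) all_evs <- c(all_evs, rep(list(evs[[i]]),
                                                        counts[i]))
    tab <- build_pattern_table(all_evs, n_total = sum(counts) + 500L)
    base <- classify_edited(tab, edit_call_config(3, 50))
    expect_lte(classify_edited(tab, edit_call_config(3, 100))$edited_reads,
               base$edited_reads)
    expect_lte(classify_edited(tab, edit_call_config(6, 50))$edited_reads,
               base$edited_reads)
    mask <- matrix(c(0L, 200L), 1)
    expect_lte(classify_edited(tab, edit_call_config(3, 50),
                               mask)$edited_reads, base$edited_reads)
  }
})

test_that("deletion-size profile covers qualifying deletions only", {
  cfg <- edit_call_config(min_pattern_reads = 100)
  ins <- data.frame(kind = "insertion", start = 60L, size = 5L, seq = "AAAAA",
                    ambiguity_end = 60L, stringsAsFactors = FALSE)
  evs <- c(rep(list(del_event(40, 6)), 150), rep(list(ins), 200),
           rep(list(del_event(80, 9)), 20))
  tab <- build_pattern_table(evs, n_total = 400L)
  res <- classify_edited(tab, cfg)
  prof <- deletion_size_profile(res)
  expect_identical(prof$size, 6L)      # insertion and sub-threshold absent
  expect_identical(prof$count, 150L)
})

test_that("normalization to a reference group behaves like a ratio", {
  eff <- c(wt1 = 0.01, wt2 = 0.03, v1 = 0.2, v2 = 0.02)
  r <- normalize_to_reference(eff, c("wt1", "wt2"))
  expect_equal(unname(r[c("wt1", "wt2")]), c(0.5, 1.5))
  expect_equal(mean(r[c("wt1", "wt2")]), 1)
  expect_equal(unname(r[["v1"]]), 10)
  expect_equal(unname(normalize_to_reference(c(a = 0.2, b = 0.2), "a")),
               c(1, 1))
  expect_error(normalize_to_reference(c(a = 0, b = 1), "a"), "zero")
})

test_that("simulate -> quantify round trip recovers the truth", {
  cfg <- sim_config(seed = 31L, n_reads = 20000L, true_efficiency = 0.05,
                    deletion_size_dist = c(`8` = 0.375, `9` = 0.375,
                                           `10` = 0.25))
  ref <- default_amplicon(cfg)
  al <- simulate_edit_alleles(ref, cfg, 100L)
  sim <- simulate_amplicon_reads(ref, al, cfg)
  q <- quantify_editing(sim$reads, ref)
  expect_gte(q$result$efficiency, qbinom(0.005, 20000, 0.05) / 20000)
  expect_lte(q$result$efficiency, qbinom(0.995, 20000, 0.05) / 20000)
  # histogram mode among the configured sizes
  prof <- q$size_profile
  expect_true(prof$size[which.max(prof$count)] %in% 8:10)
  # recovered qualifying patterns are exactly the planted keys
  planted <- sort(unique(sim$truth$pattern_key[!is.na(sim$truth$pattern_key)]))
  expect_identical(sort(q$result$qualifying_patterns$key), planted)
  expect_error(quantify_editing(character(), ref), "no reads")
})
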