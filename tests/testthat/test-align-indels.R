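test_that("identical read aligns with no indels and full match", {
  ref <- fixture_amplicon()
  a <- align_read(ref$sequence, ref)
  expect_true(a$aligned)
  expect_identical(a$n_edit_cols, 0L)
  expect_identical(nrow(extract_indels(a)), 0L)
})

test_that("a clean deletion is recovered as one event of the right size", {
  set.seed(101)
  ref <- random_dna(60)
  read <- paste0(substr(ref, 1, 30), substr(ref, 37, 60))
  a <- align_read(read, ref)
  ev <- extract_indels(a, ref)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$size, 6L)
  # rebuild the read from (start, size)
  rebuilt <- paste0(substr(ref, 1, ev$start), substr(ref, ev$start + 7, 60))
  expect_identical(rebuilt, read)
})

test_that("a substitution-only read yields zero indels", {
  set.seed(102)
  ref <- random_dna(80)
  rd <- strsplit(ref, "")[[1]]
  rd[40] <- setdiff(c("A", "C", "G", "T"), rd[40])[1]
  a <- align_read(paste(rd, collapse = ""), ref)
  expect_identical(nrow(extract_indels(a, ref)), 0L)
  expect_identical(a$n_edit_cols, 1L)
})

test_that("alignment scores match an exhaustive DP oracle on short refs", {
  set.seed(103)
  for (k in 1:25) {
    ref <- random_dna(sample(40:60, 1))
    rd <- strsplit(ref, "")[[1]]
    if (runif(1) < 0.6) {  # random deletion
      s <- sample(length(rd) - 12, 1)
      rd <- rd[-(s:(s + sample(0:9, 1)))]
    }
    if (runif(1) < 0.4) {  # random insertion
      p <- sample(length(rd), 1)
      rd <- append(rd, sample(c("A", "C", "G", "T"), sample(1:3, 1),
                              replace = TRUE), after = p)
    }
    if (runif(1) < 0.5) {  # substitutions
      p <- sample(length(rd), 2)
      rd[p] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    }
    read <- paste(rd, collapse = "")
    a <- align_read(read, ref)
    expect_equal(a$score, oracle_align_score(read, ref))
  }
})

test_that("reads failing the alignability rules are flagged", {
  ref <- fixture_amplicon()
  short <- substr(ref$sequence, 1, floor(nchar(ref$sequence) / 2) - 5)
  expect_false(align_read(short, ref)$aligned)
  garbage <- paste(rep("A", nchar(ref$sequence)), collapse = "")
  expect_false(align_read(garbage, ref)$aligned)
})

test_that("left-normalization shifts an indel to its smallest start", {
  # A-run at 0-based 10..13; deleting any one A is the same pattern
  ref <- paste0("CGTCGTCGTC", "AAAA", "GTCGTCGTCG")
  rd <- strsplit(ref, "")[[1]][-13]  # delete the A at 0-based position 12
  a <- align_read(paste(rd, collapse = ""), ref)
  ev <- extract_indels(a, ref)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$start, 10L)
  expect_identical(ev$ambiguity_end, 13L)
  # idempotence: the normalized event does not move again
  ev2 <- ampliscreen:::.normalize_deletion(strsplit(ref, "")[[1]],
                                           ev$start, ev$size)
  expect_identical(ev2$start, ev$start)
  expect_identical(ev2$ambiguity_end, ev$ambiguity_end)
})

test_that("insertions left-normalize with sequence rotation", {
  ref <- paste0("CGTCGTCGTC", "AAAA", "GTCGTCGTCG")
  rd <- strsplit(ref, "")[[1]]
  rd <- append(rd, "A", after = 12)  # extra A inside the run
  a <- align_read(paste(rd, collapse = ""), ref)
  ev <- extract_indels(a, ref)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "insertion")
  expect_identical(ev$start, 10L)
  expect_identical(ev$seq, "A")
})

test_that("rebuild property holds over random single deletions", {
  set.seed(104)
  for (k in 1:20) {
    ref <- random_dna(200)
    size <- sample(1:12, 1)
    s <- sample(20:150, 1)
    read <- paste0(substr(ref, 1, s), substr(ref, s + size + 1, 200))
    ev <- extract_indels(align_read(read, ref), ref)
    expect_identical(nrow(ev), 1L)
    rebuilt <- paste0(substr(ref, 1, ev$start),
                      substr(ref, ev$start + ev$size + 1, 200))
    expect_identical(rebuilt, read)
  }
})

test_that("homopolymer masks are maximal closed-boundary runs", {
  expect_identical(detect_homopolymer_masks("CCAAAAAAAAGG", 8),
                   matrix(c(2L, 10L), 1, dimnames = list(NULL, c("start", "end"))))
  expect_identical(nrow(detect_homopolymer_masks(strrep("ACGT", 10), 8)), 0L)
  # run exactly min_run long is included
  expect_identical(nrow(detect_homopolymer_masks("GTTTTTTG", 6)), 1L)
  expect_identical(nrow(detect_homopolymer_masks("GTTTTTG", 6)), 0L)
})

test_that("pattern identity is (kind, size, start) and reads count once", {
  del <- function(start, size) data.frame(
    kind = "deletion", start = start, size = size, seq = strrep("N", size),
    ambiguity_end = start, stringsAsFactors = FALSE)
  # 150 identical events -> one key with count 150
  tab <- build_pattern_table(rep(list(del(50, 6)), 150))
  expect_identical(nrow(tab$counts), 1L)
  expect_identical(tab$counts$count, 150L)
  # same size, different location -> two patterns
  tab2 <- build_pattern_table(list(del(50, 6), del(51, 6)))
  expect_identical(nrow(tab2$counts), 2L)
  expect_identical(tab2$counts$count, c(1L, 1L))
  # one read carrying a 42 bp and a 1 bp deletion increments two keys
  tab3 <- build_pattern_table(list(rbind(del(100, 42), del(83, 1))))
  expect_identical(nrow(tab3$counts), 2L)
  expect_identical(tab3$total_reads, 1L)
  # aggregation is invariant to read order
  evs <- list(del(10, 3), del(20, 5), del(10, 3), del(30, 8))
  t_a <- build_pattern_table(evs)
  t_b <- build_pattern_table(rev(evs))
  expect_identical(t_a$counts, t_b$counts)
})
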