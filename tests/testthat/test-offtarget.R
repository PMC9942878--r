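SP <- "GACGTTACAGGCTTCACGAT"

test_that("PAM matching follows the IUPAC rule on the 5' side", {
  expect_true(pam_match("TGA", "TBN"))    # B admits G
  expect_true(pam_match("TTA", "TBN"))
  expect_true(pam_match("TCC", "TBN"))
  expect_false(pam_match("TAA", "TBN"))   # B excludes A
  expect_false(pam_match("ATC", "TBN"))   # first position must be T
  expect_false(pam_match("TNA", "TBN"))   # unknown base fails B
  expect_true(pam_match("TGN", "TBN"))    # rule N admits unknown base
  expect_error(pam_match("TG", "TBN"), "length")
})

test_that("a verbatim protospacer with valid PAM is found at cost zero", {
  set.seed(201)
  g <- fixture_genome_with_site(1500, SP, at = 400)
  for (fn in c(find_sites, site_oracle)) {
    s <- fn(g, SP, "TBN", 4, 2)
    on <- s[s$start == 402 & s$strand == "+", ]
    expect_identical(nrow(on), 1L)
    expect_identical(on$mismatches, 0L)
    expect_identical(on$dna_bulge + on$rna_bulge, 0L)
    expect_identical(on$pam_seq, "TTC")
    expect_identical(on$end, 422L)
  }
})

test_that("sites beyond the mismatch budget are absent", {
  set.seed(202)
  g <- fixture_genome_with_site(800, SP, at = 300)
  gs <- strsplit(g[[1]], "")[[1]]
  # corrupt 5 spacer positions of the planted protospacer
  for (p in c(305, 308, 311, 314, 317))
    gs[p] <- setdiff(c("A", "C", "G", "T"), gs[p])[1]
  g2 <- setNames(paste(gs, collapse = ""), names(g))
  s <- find_sites(g2, SP, "TBN", 4, 2)
  expect_identical(nrow(s[s$start == 302 & s$strand == "+", ]), 0L)
  # budgets (5, 2) re-admit it
  s5 <- find_sites(g2, SP, "TBN", 5, 2)
  expect_identical(nrow(s5[s5$start == 302 & s5$strand == "+", ]), 1L)
})

test_that("a protospacer deletion is found as an RNA bulge", {
  set.seed(203)
  g <- fixture_genome_with_site(600, SP, at = 200)
  gs <- strsplit(g[[1]], "")[[1]]
  gs <- gs[-212]  # drop one protospacer base
  g2 <- setNames(paste(gs, collapse = ""), names(g))
  for (fn in c(find_sites, site_oracle)) {
    s <- fn(g2, SP, "TBN", 1, 2)
    hit <- s[s$start == 202 & s$strand == "+", ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$rna_bulge, 1L)
    expect_identical(hit$dna_bulge, 0L)
    expect_identical(hit$end, 221L)  # span one shorter than the spacer
  }
})

test_that("an extra protospacer base is found as a DNA bulge", {
  set.seed(204)
  g <- fixture_genome_with_site(600, SP, at = 200)
  gs <- strsplit(g[[1]], "")[[1]]
  gs <- append(gs, "T", after = 212)
  g2 <- setNames(paste(gs, collapse = ""), names(g))
  s <- find_sites(g2, SP, "TBN", 0, 2)
  hit <- s[s$start == 202 & s$strand == "+", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$dna_bulge, 1L)
  expect_identical(hit$end, 223L)
})

test_that("a site on the reverse strand is reported on '-' only", {
  set.seed(205)
  g <- fixture_genome_with_site(900, SP, at = 350)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", g[[1]]), "")[[1]]),
              collapse = "")
  grc <- setNames(rc, names(g))
  s <- find_sites(grc, SP, "TBN", 0, 0)
  expect_identical(unique(s$strand), "-")
  # coordinates map back to the original span
  expect_identical(s$start, 900L - 372L)
  expect_identical(s$end, 900L - 352L)
})

test_that("find_sites equals the oracle on random instances", {
  set.seed(206)
  for (k in 1:20) {
    g <- fixture_genome_with_site(1200, SP, at = sample(300:700, 1))
    expect_identical(site_identity(find_sites(g, SP, "TBN", 4, 2)),
                     site_identity(site_oracle(g, SP, "TBN", 4, 2)))
  }
})

test_that("budget monotonicity: smaller budgets give subset results", {
  set.seed(207)
  for (k in 1:8) {
    g <- fixture_genome_with_site(1000, SP, at = 400)
    # locus identity by PAM anchor: the protospacer-start side is fixed,
    # the far end can legitimately shift when a larger budget admits a
    # cheaper bulged layout
    anchor_id <- function(s)
      paste(s$chrom, s$strand, ifelse(s$strand == "+", s$start, s$end))
    wide <- anchor_id(find_sites(g, SP, "TBN", 4, 2))
    for (budgets in list(c(2, 1), c(3, 0), c(4, 1), c(0, 0))) {
      narrow <- anchor_id(find_sites(g, SP, "TBN", budgets[1], budgets[2]))
      expect_true(all(narrow %in% wide))
    }
  }
})

test_that("strand symmetry: reverse-complementing the genome swaps strands", {
  set.seed(208)
  g <- fixture_genome_with_site(1100, SP, at = 500)
  rc <- setNames(paste(rev(strsplit(chartr("ACGT", "TGCA", g[[1]]), "")[[1]]),
                       collapse = ""), names(g))
  a <- find_sites(g, SP, "TBN", 3, 1)
  b <- find_sites(rc, SP, "TBN", 3, 1)
  expect_identical(nrow(a), nrow(b))
  expect_identical(sort(paste(a$mismatches, a$dna_bulge, a$rna_bulge)),
                   sort(paste(b$mismatches, b$dna_bulge, b$rna_bulge)))
  # spans map through the coordinate reflection
  glen <- nchar(g[[1]])
  expect_identical(sort(glen - a$end), sort(b$start))
})

test_that("genome Ns match no spacer base and only the N PAM class", {
  g <- c(chr = paste0(strrep("C", 50), "TTC", SP, strrep("C", 50)))
  gn <- g
  substr(gn[[1]], 56, 58) <- "NNN"  # three protospacer bases -> N
  a <- find_sites(gn, SP, "TBN", 2, 0)
  expect_identical(nrow(a[a$strand == "+" & a$start == 53, ]), 0L)
  b <- find_sites(gn, SP, "TBN", 3, 0)
  expect_identical(b[b$strand == "+" & b$start == 53, ]$mismatches, 3L)
  # N inside the PAM fails the B class
  gp <- g
  substr(gp[[1]], 52, 52) <- "N"
  expect_identical(nrow(find_sites(gp, SP, "TBN", 0, 0)), 0L)
})

test_that("empty and edge genomes produce no sites", {
  expect_identical(nrow(find_sites(c(x = "ACGTACGTACGTACGT"), SP, "TBN",
                                   4, 2)), 0L)
  # PAM at the contig edge without a full protospacer is not reported
  g <- c(x = paste0("TTC", substr(SP, 1, 10)))
  expect_identical(nrow(find_sites(g, SP, "TBN", 0, 0)), 0L)
})
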