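---
title: "Models and design choices in ampliscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ampliscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscreen)
```

ampliscreen implements three connected analyses for staggered-cut CRISPR
nucleases: quantifying editing efficiency from deep amplicon sequencing,
enumerating candidate off-target sites under a 5′ PAM rule, and screening
whole-genome variant call sets for off-target edits. This vignette is the
package's account of the underlying models, the parameters that matter,
and the places where the design was genuinely open and a choice had to be
made.

## Edited-read classification

### The model

A sequencing read from an edited cell carries a deletion (occasionally an
insertion) at the repair junction of the nuclease cut. A read from an
unedited cell should match the amplicon — but PCR polymerase slippage and
sequencing error generate spurious indels, overwhelmingly of 1–2 bp and
concentrated in homopolymer runs, and these can recur in *many* reads at
deep coverage because they are sequence-driven, not random. Control
samples therefore show 1–2 bp indel patterns with read counts above 100,
while genuinely larger indels appear only at trace frequencies. The
classification rule inverts these observations:

* a **pattern** is an indel identified by (kind, size, left-normalized
  start) — inserted/deleted sequence content is deliberately not part of
  the identity, only size and location;
* a pattern is trusted as an edit iff its size is ≥ `min_indel_size`
  (default 3 bp) **and** its read support is ≥ `min_pattern_reads`
  (default 100 at the typical 1–5 million-read depth; 10 is the
  documented adjustment for shallow runs below ~10⁵ reads) **and** it is
  not confined to a homopolymer mask;
* a read is **edited** when it carries at least one qualifying pattern,
  counted once however many it carries (a real multi-deletion allele —
  e.g. a 42 bp deletion with a second 1 bp deletion upstream — increments
  two patterns but one read);
* efficiency = edited / total aligned reads; reports round the percentage
  to two significant figures, raw fractions are always retained.

The rule trades sensitivity for specificity: a true edit whose size class
is rare at the sequenced depth (support < 100 reads) is *not* counted.
The `analysis/02` driver shows exactly this on simulated data with a
long-tailed deletion-size distribution.

### Alignment and normalization

Reads are aligned end-to-end (global) with affine gaps: match +2,
mismatch −4, gap open 10, gap extension 1. The heavy open cost keeps an
8–10 bp repair deletion as a single gap instead of fragmenting it; the
exact tie-break (diagonal, then deletion, then insertion during
traceback) is deterministic but immaterial, because every extracted indel
is then **left-normalized** — shifted to the smallest reference start
that produces an identical alternate sequence — and the rightmost
equivalent start is kept as the ambiguity bound. Pattern identity is
computed only from normalized events, which makes it robust to scoring
details. Reads shorter than half the reference, or whose optimal
alignment exceeds `max_edit_frac` (default 0.25) edited columns, are
excluded from numerator *and* denominator and counted separately.

Masking uses the ambiguity bound: an indel is homopolymer-confined only
if its whole range `[start, ambiguity_end + size)` (deletions; the
analogous boundary set for insertions) fits inside a single mask
interval. Partial overlap does not mask — an 8 bp deletion that merely
touches a poly-A run is still an edit. The run-length threshold
`min_homopolymer_run = 8` bp generalizes the poly-A problem to any base;
no published number exists for "long stretches", so 8 bp is this
package's documented choice (at 0.1% per-base error, slippage below that
length rarely reaches the read-count threshold anyway).

## The amplicon simulator

The generator emulates the read structure the classification rule was
designed against, at the study's own scale:

* **depth and effect**: 200,000 reads with `true_efficiency = 0.011` is
  the configuration exercised throughout the tests (the field's runs are
  10⁵–10⁶ reads; 2 × 10⁵ keeps the suite minutes-scale while leaving the
  binomial CI width at ±0.06 percentage points);
* **deletion sizes**: repair of an 8–12 nt 5′-overhang staggered cut
  concentrates deletions at 8–10 bp; the default distribution puts 80%
  of its mass there with light 3–12 bp tails. Deletion midpoints sit at
  the protospacer 3′ end + `cut_offset` (default −4 bp, i.e. inside the
  protospacer, PAM-distal). The cut *chemistry* is known but the repair
  junction coordinate is not published, so `cut_offset` is an exposed,
  documented guess;
* **noise**: substitutions at 0.001/bp; a spurious 1–2 bp indel per read
  with probability 0.002 at a uniform position; an extra 1 bp slip per
  overlapped homopolymer run (≥ 6 bp) with probability 0.003 — this
  concentration is what reproduces the "1–2 bp patterns with >100 reads"
  phenomenon in noise-only runs while leaving indels ≥ 3 bp below any
  plausible threshold. Noise indels above 2 bp are excluded by default
  and available as a stress option;
* **reads are full-length amplicon copies**: no fragmentation, pairing or
  quality modeling — the analysis operates on merged amplicon sequence,
  so fragment structure would add nothing testable.

What passing tests on this generator do **not** show: robustness to
quality-dependent error profiles, chimeric PCR products, large
rearrangements, or substitution-based editing outcomes — real data
contains all four and this package does not model them.

Every generator draws from a substream derived from
(`seed`, stage label), so adding one simulation stage never perturbs
another stage's draws, and every simulator is a pure function of its
configuration.

## Off-target site search

A candidate site is a genomic window, on either strand, whose 5′-adjacent
triplet satisfies the IUPAC PAM rule (default `TBN`; an unknown genome
base fails every class except the rule's own `N`) and whose alignment to
the spacer stays within 4 mismatches and a 2 bp bulge. Bulge semantics
were a genuinely open point and are resolved as: **one contiguous bulge
of one type per site** — a DNA bulge (extra protospacer bases) *or* an
RNA bulge (extra spacer bases) of at most `max_bulge` bases, never inside
the PAM and never at the spacer ends. Scattered bulges or opposite-type
pairs are not admitted: an RNA/DNA bulge pair could excise a mismatched
spacer base at cost 2, quietly readmitting sites with five substitutions,
and does not correspond to a physical guide–target duplex geometry. This
matches the convention of the standard prediction tools at these budget
settings.

Within a window the reported alignment is the lexicographic minimum of
(mismatches + bulged bases, bulged bases, DNA-bulge bases, bulge position
sum) — a total order, so any correct algorithm returns the same answer.
That is what makes the two independent implementations comparable:
`find_sites` (PAM pre-scan plus a constrained dynamic program in C++, the
production path) and `site_oracle` (pure-R enumeration of every bulge
layout at every PAM-anchored window, refused above 10 kb) must agree
exactly, field by field, and the test suite checks this on hundreds of
random genome/spacer instances.

## The screening cascade

The cascade consumes normalized variant records — one row per
(chrom, pos, ref, alt), multiallelics split with per-allele depths — and
applies, in order: two-caller intersection on that identity key; hard
filters (SNPs: QD < 2.0, FS > 60.0, MQ < 40.0, SOR > 4.0; indels:
QD < 2.0, FS > 200.0, SOR > 10.0; a record lacking an annotation passes
that criterion, since the second caller emits none); background-line
subtraction on the identity key; coverage ≥ 30 reads (AD sum when
present, else DP) with Ref/Alt ≤ 3, both comparisons strict as stated and
zero variant reads counting as infinite ratio; simple-repeat masking; and
finally overlap of survivors with predicted off-target spans padded by
`offtarget_window = 20` bp, enough to catch staggered-cut junction
variants just outside the protospacer.

The repeat filter is a deterministic replacement for manual inspection:
a variant is removed when its interval, extended over its
left-normalization ambiguity range, lies entirely within one
mononucleotide run ≥ 10 bp or one perfect dinucleotide tandem ≥ 6 units.
The run-length thresholds are this package's choices (the original triage
was manual and published no numbers); both are configurable, and
containment — not overlap — is the rule, so variants at repeat edges
survive.

**Detection power.** The Ref/Alt > 3 rule costs sensitivity for true
heterozygotes: with K ~ Binomial(n, ½) variant reads at coverage n, the
miss probability is P(K < n/4) — `pbinom(ceiling(n/4) - 1, n, 0.5)` —
which is 0.0026 (0.26%) at n = 30 and vanishes with depth. Note this
miss probability *decreases* as the tolerated ratio grows (a more
tolerant filter discards fewer heterozygotes); the suite pins the
closed form to an explicit summation oracle for all n ≤ 64.

## The WGS call-set simulator

Call sets are simulated directly (no read-level modeling): a toy genome
(2 × 50 kb with embedded homopolymer runs and dinucleotide tandems every
~5 kb), shared background variants present in all three call sets,
spontaneous private mutations and planted heterozygous edits present in
both caller sets only, and one artifact class per cascade stage:
caller-private calls, shared calls with failing annotations, low
allele-fraction calls, low-coverage calls, and 1 bp slippage deletions
inside repeat runs. True calls draw QD ~ N(25, 4), FS ~ Exp(mean 3),
MQ ~ N(60, 1.5) and SOR ~ Gamma(2, rate 4), passing all hard filters with
probability ≈ 1 − 10⁻⁵ (the SOR tail is the binding constraint; a heavier
tail would make true-call survival a coin flip at the per-mille level,
contradicting the model's own ≥ 99%-pass design target). Artifact calls
always carry at least one failing annotation (`artifact_fail_prob = 1`;
lowering it is a stress option that leaks annotation-clean artifacts into
the final set, as real data does). Planted heterozygotes draw allele
fractions of 0.5 at Poisson(`mean_depth` = 60) coverage. True variant
loci are placed clear of repeat context; planted loci are reserved first,
so collisions are impossible by construction rather than by rejection.

The deliberate simplifications: no linkage between records, no
multi-sample genotype likelihoods, no mapping-driven artifact
correlation between the two "callers", and annotation distributions that
are independent across records. The cascade's set-algebra and threshold
behavior is fully exercised; a caller's systematic failure modes are not.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; 1-based only at the VCF
  boundary. BED output is 0-based half-open.
* `signif(100 * fraction, 2)` is the single reporting rule for
  percentages.
* Empty pattern tables classify to efficiency 0 with a warning; an empty
  read set is an error; `total = 0` makes efficiency undefined (error).
* An empty background set subtracts nothing, with a warning.
* Records with neither AD nor DP cannot be depth-filtered and are removed
  with a logged reason.
* Duplicate records from one caller deduplicate on the identity key.
* Seeds derived from labels stay below 2³¹; reruns with equal
  configuration are byte-identical (manifests record parameters, seeds
  and output checksums).

## Problem sizes used by the test suite

Chosen as the package's own validation scale: amplicon recovery at
200,000 reads (one seed) with twenty 200,000-read noise-only controls;
search-vs-oracle agreement on 200 random 5 kb genomes at budgets (4, 2);
100 screening replicates with planted edits plus 20 background-only
replicates; and randomized monotonicity suites over classification
thresholds, masks, budgets and filter stages. The acceptance script
(`scripts/acceptance.R`) recomputes the headline numbers at the same
scales from a single command-line seed.

## Known limitations

* Substitution-based edits (base editing) are out of scope by design;
  the classifier only sees indel patterns.
* The ≥ 100-read pattern threshold makes the efficiency estimate a
  *lower* bound when the size distribution is long-tailed relative to
  depth (shown in `analysis/02`); this mirrors the original criterion
  rather than correcting it.
* The off-target search is exact but index-free: kilobase-to-megabase
  toy genomes are the intended scale, not full plant genomes.
* `site_oracle` is deliberately slow and refuses genomes above 10 kb.
* Insertion pattern identity ignores inserted sequence content (size and
  location only). Whether the original analysis distinguished content
  is unknowable from its description; size+location is the stated rule.
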