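#!/usr/bin/env Rscript

# Stage 1: simulate a deep amplicon sequencing run at the study's
# conditions — 200,000 reads of a 250 bp amplicon, ~1.1% of reads carrying
# a staggered-cut repair deletion (sizes concentrated at 8-10 bp) at the
# guide target, plus substitution noise, sporadic 1-2 bp indels and
# homopolymer slippage. Raw reads go to scratch/ (they are bulky and fully
# regenerable); the truth table and manifest go to results/.

suppressPackageStartupMessages(library(ampliscreen))

SEED <- 104L
raw_dir <- "scratch/amplicon"
out_dir <- "results/amplicon"
dir.create(raw_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = SEED, n_reads = 200000L, true_efficiency = 0.011)
ref <- default_amplicon(cfg)
alleles <- simulate_edit_alleles(ref, cfg, 300L)
sim <- simulate_amplicon_reads(ref, alleles, cfg)

write_fasta(setNames(ref$sequence, ref$id), file.path(raw_dir, "reference.fa"))
write_fastq(sim$reads, file.path(raw_dir, "reads.fastq"))
write_truth_tsv(sim$truth, file.path(raw_dir, "truth.tsv"))

truth_summary <- as.data.frame(table(label = sim$truth$label))
write_truth_tsv(truth_summary, file.path(out_dir, "truth_summary.tsv"))
record_manifest("simulate_amplicon",
                params = list(seed = SEED, n_reads = cfg$n_reads,
                              true_efficiency = cfg$true_efficiency,
                              guide = ref$guide$spacer),
                outputs = c(file.path(raw_dir, c("reference.fa",
                                                 "reads.fastq", "truth.tsv")),
                            file.path(out_dir, "truth_summary.tsv")),
                manifest_path = file.path(out_dir, "manifest.json"))

print(sim)
cat("planted deletion patterns:",
    paste(sort(unique(sim$truth$pattern_key[!is.na(sim$truth$pattern_key)])),
          collapse = ", "), "\n")
cat("raw reads in", raw_dir, "- summaries in", out_dir, "\n")
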