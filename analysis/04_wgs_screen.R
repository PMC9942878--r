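#!/usr/bin/env Rscript

# Stage 4: the whole-genome off-target screening cascade. Simulates two
# caller call sets for an edited plant carrying heterozygous edits planted
# at two predicted off-target loci, plus a background-line call set; runs
# two-caller intersection -> hard filters -> background subtraction ->
# coverage/allele-balance filter -> simple-repeat masking -> overlap with
# the stage-3 predicted sites.

suppressPackageStartupMessages(library(ampliscreen))

SEED <- 104L
ot_dir <- "results/offtarget"
out_dir <- "results/screen"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
if (!file.exists("scratch/offtarget/toy_genome.fa"))
  stop("run analysis/03_offtarget_search.R first")

genome <- read_fasta("scratch/offtarget/toy_genome.fa")
bed <- read.table(file.path(ot_dir, "predicted_sites.bed"), sep = "\t")
sites <- data.frame(chrom = bed$V1, start = bed$V2, end = bed$V3,
                    name = bed$V4, strand = bed$V6, mismatches = bed$V5,
                    dna_bulge = bed$V7, rna_bulge = bed$V8, pam_seq = bed$V9)

planted <- data.frame(chrom = c("chr1", "chr2"), pos = c(10010L, 20010L))
cfg <- wgs_sim_config(seed = SEED, planted_edits = planted, mean_depth = 60)
sim <- simulate_wgs_callsets(cfg, genome = genome)
print(sim)

write_vcf_records(split_and_key(sim$a), file.path(out_dir, "caller_a.vcf"),
                  "edited_plant")
write_vcf_records(split_and_key(sim$b), file.path(out_dir, "caller_b.vcf"),
                  "edited_plant")
write_vcf_records(split_and_key(sim$background),
                  file.path(out_dir, "background.vcf"), "background_line")
write_truth_tsv(sim$truth, file.path(out_dir, "truth.tsv"))

report <- screen_variants(sim$a, sim$b, sim$background, genome, sites)
print(report)

write.table(report$stages, file.path(out_dir, "stage_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(report$overlaps, file.path(out_dir, "site_overlaps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_vcf_records(report$variants, file.path(out_dir, "final_variants.vcf"),
                  "edited_plant")

surv <- merge(data.frame(key = report$variants$key), sim$truth, by = "key")
cat("final survivors by truth label:\n")
print(table(surv$label))
pl_keys <- sim$truth$key[sim$truth$label == "planted"]
cat(sprintf("planted edits recovered at predicted sites: %d of %d\n",
            length(unique(report$overlaps$key[report$overlaps$key %in%
                                                pl_keys])),
            nrow(planted)))

record_manifest("wgs_screen",
                params = list(seed = SEED, mean_depth = 60,
                              min_coverage = 30, max_ref_alt_ratio = 3),
                outputs = file.path(out_dir, c("caller_a.vcf", "caller_b.vcf",
                                               "background.vcf",
                                               "stage_counts.tsv",
                                               "site_overlaps.tsv",
                                               "final_variants.vcf")),
                manifest_path = file.path(out_dir, "manifest.json"))
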