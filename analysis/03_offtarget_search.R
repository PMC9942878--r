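#!/usr/bin/env Rscript

# Stage 3: genome-wide off-target candidate search. Builds the toy genome
# used by the screening stage, embeds one perfect and one degenerate
# protospacer for the guide, and enumerates every PAM-anchored window
# within 4 mismatches and a 2 bp bulge. On a small genome the production
# search is also cross-checked against the exhaustive oracle.

suppressPackageStartupMessages(library(ampliscreen))

SEED <- 104L
out_dir <- "results/offtarget"
raw_dir <- "scratch/offtarget"   # the genome FASTA is bulky and regenerable
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(raw_dir, recursive = TRUE, showWarnings = FALSE)

spacer <- "GACGTTACAGGCTTCACGAT"
cfg <- wgs_sim_config(seed = SEED)
genome <- simulate_toy_genome(cfg)
near <- spacer
substr(near, 4, 4) <- "A"; substr(near, 15, 15) <- "A"
substr(genome[["chr1"]], 10000, 10022) <- paste0("TTC", spacer)
substr(genome[["chr2"]], 20000, 20022) <- paste0("TGC", near)

write_fasta(genome, file.path(raw_dir, "toy_genome.fa"))
sites <- find_sites(genome, spacer, "TBN", max_mismatch = 4, max_bulge = 2)
write_sites_bed(sites, file.path(out_dir, "predicted_sites.bed"))

cat(sprintf("%d candidate site(s) for %s (TBN PAM, <=4 mm, <=2 bp bulge)\n",
            nrow(sites), spacer))
print(table(mismatches = sites$mismatches))
on <- sites[sites$mismatches == 0 & sites$dna_bulge + sites$rna_bulge == 0, ]
cat(sprintf("on-target locus: %s:%d-%d (%s), PAM %s\n", on$chrom[1],
            on$start[1], on$end[1], on$strand[1], on$pam_seq[1]))

# oracle cross-check at test scale
small <- vapply(genome, substr, "", 1, 8000)
a <- find_sites(small, spacer, "TBN", 4, 2)
b <- site_oracle(small, spacer, "TBN", 4, 2)
cols <- c("chrom", "start", "end", "strand", "mismatches", "dna_bulge",
          "rna_bulge", "pam_seq")
stopifnot(identical(sort(do.call(paste, a[cols])),
                    sort(do.call(paste, b[cols]))))
cat("production search agrees with the exhaustive oracle on the 8 kb subset\n")

record_manifest("offtarget_search",
                params = list(seed = SEED, spacer = spacer, pam = "TBN",
                              max_mismatch = 4, max_bulge = 2),
                outputs = c(file.path(raw_dir, "toy_genome.fa"),
                            file.path(out_dir, "predicted_sites.bed")),
                manifest_path = file.path(out_dir, "manifest.json"))
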