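#' Write/read amplicon simulation files
#'
#' Plain-text interchange for the simulators: FASTA for references and
#' genomes (via Biostrings), FASTQ with constant dummy qualities `'I'` for
#' simulated reads, TSV for truth tables, and a minimal VCF v4.2 subset
#' for simulated call sets (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT
#' sample, with AD/DP in the genotype field and QD/FS/MQ/SOR INFO keys).
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' @rdname write_fasta
#' @param reads character vector of read sequences.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  ids <- sprintf("read%06d", seq_len(n))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(l)
    paste(rep("I", l), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write a variant data.frame as a minimal VCF v4.2 subset
#'
#' @param records variant data.frame (see [split_and_key()] for columns).
#' @param path output file.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf_records <- function(records, path, sample_name = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant Confidence/Quality by Depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled p-value using Fisher's exact test to detect strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS Mapping Quality\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric Odds Ratio of 2x2 contingency table to detect strand bias\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  if (nrow(records)) {
    ann <- function(key, val) ifelse(is.na(val), NA_character_,
                                     sprintf("%s=%.4g", key, val))
    info <- apply(cbind(ann("QD", records$qd), ann("FS", records$fs),
                        ann("MQ", records$mq), ann("SOR", records$sor)),
                  1L, function(r) {
                    r <- r[!is.na(r)]
                    if (length(r)) paste(r, collapse = ";") else "."
                  })
    gt <- sprintf("0/1:%d,%d:%d", records$ad_ref, records$ad_alt, records$dp)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AD:DP\t%s",
                       records$chrom, records$pos, records$ref, records$alt,
                       info, gt), con)
  }
  invisible(path)
}

#' Read a VCF into a variant data.frame
#'
#' Parses a VCF (via vcfR) into the flat record layout the screening
#' cascade consumes: one row per ALT allele with AD-derived depths and any
#' QD/FS/MQ/SOR annotations found in INFO.
#'
#' @param path VCF file.
#' @param caller provenance tag stored on each record.
#' @return normalized variant data.frame (via [split_and_key()]).
#' @export
read_vcf_records <- function(path, caller = NA_character_) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF files requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix)) || nrow(fix) == 0L)
    return(split_and_key(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character())))
  num <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else x
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad_ref <- ad_alt <- rep(NA_character_, nrow(fix))
  if (!is.null(ad)) {
    parts <- strsplit(ad[, 1L], ",")
    ad_ref <- vapply(parts, function(p) p[1L], character(1))
    ad_alt <- vapply(parts, function(p)
      paste(p[-1L], collapse = ","), character(1))
  }
  split_and_key(data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    ad_ref = suppressWarnings(as.integer(ad_ref)), ad_alt = ad_alt,
    dp = if (is.null(dp)) NA_integer_ else as.integer(dp[, 1L]),
    qd = num("QD"), fs = num("FS"), mq = num("MQ"), sor = num("SOR"),
    caller = caller, stringsAsFactors = FALSE))
}

#' @rdname write_fasta
#' @param truth a truth data.frame from a simulator.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
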