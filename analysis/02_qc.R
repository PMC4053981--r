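#!/usr/bin/env Rscript
# Stage 2: sample quality control on the query cohort.
#
# Call-rate filter (>= 90%), sex check from X-chromosome homozygosity
# (markers with MAF > 0.1), and duplicate detection by method-of-moments
# IBD (PI_HAT >= 0.95). Reads stage-1 files; writes the QC tables.

suppressPackageStartupMessages(library(ancestrycheck))
data_dir <- "results/analysis/data"
out <- "results/analysis"

query <- read_vcf(file.path(data_dir, "query.vcf"))
xg <- read_vcf(file.path(data_dir, "query_x.vcf"))
sex_tab <- utils::read.table(file.path(data_dir, "reported_sex.tsv"),
                             header = TRUE, colClasses = "character")
reported <- stats::setNames(sex_tab$reported_sex, sex_tab$sample)

qc <- qc_report(query, x_genotypes = xg, reported_sex = reported)
write_tsv(qc$samples, file.path(out, "qc_samples.tsv"))
write_tsv(qc$ibd[qc$ibd$pi_hat >= 0.95, ],
          file.path(out, "qc_duplicate_pairs.tsv"))
writeLines(qc$keep, file.path(out, "qc_keep.txt"))

truth_pairs <- utils::read.table(file.path(data_dir, "planted_duplicates.tsv"),
                                 header = TRUE, colClasses = "character")
found <- sum(!qc$samples$pass & qc$samples$reason == "duplicate")
cat(sprintf("call rate: mean %.4f, %d failure(s) below 0.90\n",
            mean(qc$samples$call_rate),
            sum(qc$samples$reason == "low_call_rate")))
cat(sprintf("sex check: %d mismatch(es) between reported and inferred sex\n",
            sum(qc$samples$sex_mismatch)))
cat(sprintf("duplicates: %d planted, %d removed via PI_HAT >= 0.95\n",
            nrow(truth_pairs), found))
cat(sprintf("kept %d of %d query samples\n", length(qc$keep),
            nrow(qc$samples)))
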