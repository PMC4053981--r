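#!/usr/bin/env Rscript
# Stage 1: simulate the study data.
#
# Builds a five-superpopulation reference panel under the Balding-Nichols
# model (FST 0.05-0.15, mild LD) and a 500-person query cohort drawn from
# the same population frequencies, including planted Multiracial
# respondents, duplicates and missingness. Writes everything as VCF + TSV
# under results/analysis/data/ so the later stages can run from disk.

suppressPackageStartupMessages(library(ancestrycheck))
seed <- 1L
out <- "results/analysis/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sups <- c("AFR", "EUR", "ASN", "AMR", "SAN")
fst <- c(0.05, 0.08, 0.10, 0.12, 0.15)
pops <- lapply(seq_along(sups), function(i) {
  population_spec(paste0("P_", sups[i]), sups[i], fst[i], 60)
})
pan <- simulate_panel(sim_config(pops, n_markers = 1600, ld_block_size = 2,
                                 seed = seed))

qspec <- c(
  lapply(sups, function(s) list(population = paste0("P_", s), n = 90)),
  list(list(pop_a = "P_EUR", pop_b = "P_AFR", fraction = 0.5, n = 30,
            ethnicity = "Non-Hispanic", race = "Multiracial"),
       list(population = "P_SAN", n = 20,
            ethnicity = "Non-Hispanic", race = "Multiracial")))
q <- simulate_query(pan$panel, qspec, seed = seed + 1L)
qg <- inject_missing_and_duplicates(q$genotypes, missing_rate = 0.01,
                                    n_duplicates = 3, seed = seed + 2L)
pairs <- attr(qg, "duplicate_pairs")
report <- q$report
extra <- report[match(pairs$original, report$sample), ]
extra$sample <- pairs$duplicate
report <- rbind(report, extra)

write_vcf(pan$panel$genotypes, file.path(out, "reference.vcf"))
write_vcf(qg, file.path(out, "query.vcf"))
write_tsv(data.frame(sample = pan$panel$genotypes$samples,
                     population = pan$panel$population,
                     superpopulation = pan$panel$superpopulation),
          file.path(out, "reference_labels.tsv"))
write_tsv(report, file.path(out, "self_report.tsv"))
write_tsv(q$truth, file.path(out, "query_truth.tsv"))
write_tsv(pairs, file.path(out, "planted_duplicates.tsv"))

sexes <- stats::setNames(rep(c("male", "female"),
                             length.out = n_samples(qg)), qg$samples)
xg <- simulate_x_chromosome(sexes, 2000, seed = seed + 3L)
write_vcf(xg, file.path(out, "query_x.vcf"))
write_tsv(data.frame(sample = names(sexes), reported_sex = unname(sexes)),
          file.path(out, "reported_sex.tsv"))

cat(sprintf(
  "simulated %d reference samples (5 populations), %d query samples, %d autosomal + %d X markers\n",
  n_samples(pan$panel$genotypes), n_samples(qg), n_markers(qg),
  n_markers(xg)))
cat(sprintf("planted: %d duplicates, 1%% missingness, 50 Multiracial respondents\n",
            nrow(pairs)))
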