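#!/usr/bin/env Rscript
# Stage 4: joint MDS projection and LDA classification.
#
# Clusters reference + QC-passed query genotypes at the selected AIMs with
# identity-by-state MDS, trains a linear discriminant model on the
# reference samples' top 20 components, and assigns each query its most
# similar superpopulation with ranked posteriors.

suppressPackageStartupMessages(library(ancestrycheck))
data_dir <- "results/analysis/data"
out <- "results/analysis"

ref <- read_vcf(file.path(data_dir, "reference.vcf"))
labels <- read_labels_tsv(file.path(data_dir, "reference_labels.tsv"))
query <- read_vcf(file.path(data_dir, "query.vcf"))
keep <- readLines(file.path(out, "qc_keep.txt"))
query <- subset_genotypes(query, samples = keep)
scores <- utils::read.table(file.path(out, "marker_scores.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
aims <- scores$id[scores$selected]

proj <- project_joint(ref, query, marker_ids = aims, n_components = 20)
coords <- proj$mds$coordinates
write_tsv(data.frame(sample = proj$mds$samples,
                     reference = proj$is_reference, coords),
          file.path(out, "mds_coordinates.tsv"))

sup <- labels$superpopulation[match(
  proj$mds$samples[proj$is_reference], labels$sample)]
model <- fit_lda(coords[proj$is_reference, , drop = FALSE], sup)
assignments <- predict(model, coords[!proj$is_reference, , drop = FALSE])
write_tsv(as.data.frame(assignments), file.path(out, "assignments.tsv"))

truth <- utils::read.table(file.path(data_dir, "query_truth.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
m <- match(assignments$sample, truth$sample)
pure <- !is.na(m) & truth$admixture_fraction[m] == 1
acc <- mean(assignments$best[pure] == truth$superpopulation[m][pure])
cat(sprintf("MDS: %d samples x %d components; leading eigenvalues %s\n",
            length(proj$mds$samples), ncol(coords),
            paste(signif(head(proj$mds$eigenvalues, 3), 3), collapse = ", ")))
cat(sprintf("assignment accuracy on pure-ancestry queries: %.1f%% (n = %d)\n",
            100 * acc, sum(pure)))
cat(sprintf("admixed queries (50/50 EUR-AFR) best-assigned: %s\n",
            paste(names(table(assignments$best[!pure & !is.na(m) &
              grepl("x", truth$population[m])])), collapse = ", ")))
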