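#!/usr/bin/env Rscript
# Stage 5: concordance of genetic ancestry with self-report.
#
# Cross-tabulates the query assignments against self-reported ethnicity
# and race, scores concordance under the expected-match mapping, and
# profiles the no-prediction (Multiracial / Non-Hispanic Other) subgroup.
# Also recomputes the same statistics on the packaged published
# cross-tabulation for comparison.

suppressPackageStartupMessages(library(ancestrycheck))
data_dir <- "results/analysis/data"
out <- "results/analysis"

report <- read_self_report_tsv(file.path(data_dir, "self_report.tsv"))
assignments <- utils::read.table(file.path(out, "assignments.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
ct <- build_crosstab(report, assignments)
write_tsv(as.data.frame(ct), file.path(out, "crosstab.tsv"))
st <- concordance_stats(ct)
jsonlite::write_json(
  list(n_evaluable = st$n_evaluable, n_concordant = st$n_concordant,
       n_discordant = st$n_discordant, rate_pct = st$rate_pct,
       no_prediction = list(n = st$no_prediction$n,
                            distribution = as.list(st$no_prediction$distribution))),
  file.path(out, "concordance_stats.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("simulated cohort: %d/%d (%.1f%%) concordant\n",
            st$n_concordant, st$n_evaluable, st$rate_pct))
cat(sprintf("no-prediction subgroup: %d samples; superpopulation profile: %s\n",
            st$no_prediction$n,
            paste(names(st$no_prediction$distribution),
                  st$no_prediction$distribution, collapse = ", ")))

pub <- concordance_stats(published_crosstab())
cat(sprintf("published cohort (packaged table): %d/%d (%.1f%%) concordant; no-prediction n = %d\n",
            pub$n_concordant, pub$n_evaluable, pub$rate_pct,
            pub$no_prediction$n))
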