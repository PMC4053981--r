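# Concordance between self-reported ethnicity/race and assigned genetic
# ancestry: expected-match mapping, cross-tabulation, and summary
# statistics, including the no-prediction (Multiracial / Non-Hispanic
# Other) subgroup profile.

superpop_levels <- function() c("AFR", "EUR", "ASN", "AMR", "SAN")

#' Default expectation map from self-report stratum to superpopulation set
#'
#' Thirteen (ethnicity, race) strata, each mapped to the set of reference
#' superpopulations a concordant assignment may fall in. Hispanic strata
#' generally admit AMR alongside the race-implied group (e.g. Hispanic
#' African American maps to \{AFR, AMR\}); self-reported Asian admits both
#' East (ASN) and South (SAN) Asian ancestry because the questionnaire has
#' a single Asian category. Multiracial strata and Non-Hispanic Other map
#' to the empty set: no prediction is expected and these samples are
#' excluded from concordance denominators.
#'
#' @return An object of class `expectation_map`: data.frame with
#'   `ethnicity`, `race`, and list-column `expected`.
#' @export
default_expectation_map <- function() {
  strata <- list(
    list("Hispanic",     "African American",                          c("AFR", "AMR")),
    list("Non-Hispanic", "African American",                          "AFR"),
    list("Hispanic",     "American Indian or Alaska Native",          "AMR"),
    list("Non-Hispanic", "American Indian or Alaska Native",          "AMR"),
    list("Non-Hispanic", "Asian",                                     c("ASN", "SAN")),
    list("Non-Hispanic", "Native Hawaiian or Other Pacific Islander", "ASN"),
    list("Hispanic",     "White",                                     c("AMR", "EUR")),
    list("Non-Hispanic", "White",                                     "EUR"),
    list("Hispanic",     "Other",                                     "AMR"),
    list("Non-Hispanic", "Other",                                     character(0)),
    list("Hispanic",     "Multiracial",                               character(0)),
    list("Non-Hispanic", "Multiracial",                               character(0)),
    list("Unknown",      "Multiracial",                               character(0))
  )
  out <- data.frame(
    ethnicity = vapply(strata, `[[`, "", 1),
    race = vapply(strata, `[[`, "", 2),
    stringsAsFactors = FALSE)
  out$expected <- lapply(strata, `[[`, 3)
  stopifnot(all(unlist(out$expected) %in% superpop_levels()))
  class(out) <- c("expectation_map", "data.frame")
  out
}

#' Look up the expected superpopulation set for one stratum
#'
#' @param map an `expectation_map`.
#' @param ethnicity,race stratum to look up.
#' @return character vector (possibly empty = no prediction).
#' @export
expected_superpops <- function(map, ethnicity, race) {
  i <- which(map$ethnicity == ethnicity & map$race == race)
  if (length(i) == 0) stop("stratum not in expectation map: ",
                           ethnicity, " / ", race)
  map$expected[[i]]
}

#' Cross-tabulate self-report strata against assigned superpopulations
#'
#' Counts each sample's best-assignment superpopulation per (ethnicity,
#' race) stratum. Strata appear in [default_expectation_map()] order,
#' followed by any additional strata present in the reports; only strata
#' with at least one sample are kept.
#'
#' @param reports a [self_report()] table covering every assigned sample.
#' @param assignments an `assignments` object (or data.frame with `sample`
#'   and `best`).
#' @return An object of class `crosstab`: data.frame with `ethnicity`,
#'   `race`, one integer column per superpopulation, and `total`.
#' @export
build_crosstab <- function(reports, assignments) {
  m <- match(assignments$sample, reports$sample)
  if (anyNA(m)) {
    stop("assignment without self-report: ",
         paste(utils::head(assignments$sample[is.na(m)], 3), collapse = ", "))
  }
  eth <- reports$ethnicity[m]
  race <- reports$race[m]
  sup_cols <- union(superpop_levels(), unique(assignments$best))
  key <- paste(eth, race, sep = " / ")
  def <- default_expectation_map()
  def_keys <- paste(def$ethnicity, def$race, sep = " / ")
  keys <- c(intersect(def_keys, key), setdiff(unique(key), def_keys))
  counts <- matrix(0L, length(keys), length(sup_cols),
                   dimnames = list(keys, sup_cols))
  if (nrow(assignments) > 0) {
    tab <- table(factor(key, levels = keys),
                 factor(assignments$best, levels = sup_cols))
    counts[] <- as.integer(tab)
  }
  parts <- strsplit(keys, " / ", fixed = TRUE)
  out <- data.frame(ethnicity = vapply(parts, `[[`, "", 1),
                    race = vapply(parts, `[[`, "", 2),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts, row.names = NULL))
  out$total <- as.integer(rowSums(counts))
  class(out) <- c("crosstab", "data.frame")
  out
}

crosstab_superpops <- function(ct) {
  setdiff(names(ct), c("ethnicity", "race", "total"))
}

#' Construct a crosstab directly from stratum counts
#'
#' For published or externally tallied tables (no genotypes needed).
#'
#' @param df data.frame with `ethnicity`, `race`, and one count column per
#'   superpopulation.
#' @return A `crosstab`.
#' @export
as_crosstab <- function(df) {
  sup <- intersect(names(df), superpop_levels())
  stopifnot(length(sup) > 0, all(c("ethnicity", "race") %in% names(df)))
  out <- df[, c("ethnicity", "race", sup)]
  for (s in sup) out[[s]] <- as.integer(out[[s]])
  if (any(unlist(out[sup]) < 0)) stop("counts must be non-negative")
  out$total <- as.integer(rowSums(out[sup]))
  class(out) <- c("crosstab", "data.frame")
  out
}

#' The published superpopulation-by-self-report cross-tabulation
#'
#' The packaged cross-tabulation of self-reported ethnicity and race
#' against best-assigned 1000 Genomes superpopulation for the 641
#' exome-array-genotyped study participants that motivated this package.
#' Ships as a plain TSV so the headline concordance numbers are testable
#' without any genotype data.
#'
#' @return A `crosstab` with the 13 published strata.
#' @export
published_crosstab <- function() {
  path <- system.file("extdata", "published_crosstab.tsv",
                      package = "ancestrycheck", mustWork = TRUE)
  as_crosstab(utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' Concordance statistics for a cross-tabulation
#'
#' Evaluable samples are those in strata with a non-empty expected set; a
#' sample is concordant iff its assigned superpopulation lies in the set.
#' The no-prediction subgroup (empty expected set) is profiled separately
#' with its superpopulation distribution.
#'
#' @param ct a `crosstab`.
#' @param map an `expectation_map`; every stratum in `ct` must be mapped.
#' @return list: `n_evaluable`, `n_concordant`, `n_discordant`, `fraction`,
#'   `rate_pct` (1 decimal place), `per_stratum` (data.frame with expected
#'   set, concordant/discordant counts), `no_prediction` (list: `n`,
#'   `distribution`).
#' @export
concordance_stats <- function(ct, map = default_expectation_map()) {
  sup <- crosstab_superpops(ct)
  n <- nrow(ct)
  conc <- disc <- integer(n)
  evaluable <- logical(n)
  exp_str <- character(n)
  for (i in seq_len(n)) {
    exp_set <- expected_superpops(map, ct$ethnicity[i], ct$race[i])
    exp_str[i] <- if (length(exp_set)) paste(exp_set, collapse = " or ")
                  else "No prediction"
    evaluable[i] <- length(exp_set) > 0
    if (evaluable[i]) {
      counts <- unlist(ct[i, sup])
      conc[i] <- sum(counts[names(counts) %in% exp_set])
      disc[i] <- sum(counts) - conc[i]
    }
  }
  n_eval <- sum(ct$total[evaluable])
  n_conc <- sum(conc)
  nopred_rows <- ct[!evaluable, sup, drop = FALSE]
  nopred_dist <- if (nrow(nopred_rows)) colSums(nopred_rows)
                 else stats::setNames(numeric(length(sup)), sup)
  per_stratum <- data.frame(ethnicity = ct$ethnicity, race = ct$race,
                            expected = exp_str, n = ct$total,
                            concordant = conc, discordant = disc,
                            stringsAsFactors = FALSE)
  list(n_evaluable = n_eval,
       n_concordant = n_conc,
       n_discordant = n_eval - n_conc,
       fraction = if (n_eval > 0) n_conc / n_eval else NA_real_,
       rate_pct = if (n_eval > 0) round(100 * n_conc / n_eval, 1) else NA_real_,
       per_stratum = per_stratum,
       no_prediction = list(n = sum(ct$total[!evaluable]),
                            distribution = nopred_dist))
}

#' Count assignments to a superpopulation set within selected strata
#'
#' @param ct a `crosstab`.
#' @param strata logical vector over `ct` rows, or a data.frame with
#'   `ethnicity` and `race` columns naming the strata to include.
#' @param superpops character vector of superpopulation labels.
#' @return list: `count`, `total` (samples in the selected strata),
#'   `fraction` (`NA` with `undefined = TRUE` when the selection is empty).
#' @export
subgroup_fraction <- function(ct, strata, superpops) {
  if (is.data.frame(strata)) {
    sel <- paste(ct$ethnicity, ct$race) %in%
      paste(strata$ethnicity, strata$race)
  } else {
    sel <- as.logical(strata)
  }
  sup <- intersect(crosstab_superpops(ct), superpops)
  rows <- ct[sel, , drop = FALSE]
  total <- sum(rows$total)
  count <- if (nrow(rows)) sum(unlist(rows[, sup, drop = FALSE])) else 0L
  list(count = as.integer(count), total = as.integer(total),
       fraction = if (total > 0) count / total else NA_real_,
       undefined = total == 0)
}
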