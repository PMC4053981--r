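test_that("the default expectation map encodes the thirteen strata", {
  map <- default_expectation_map()
  expect_equal(nrow(map), 13)
  expect_setequal(expected_superpops(map, "Non-Hispanic", "White"), "EUR")
  expect_setequal(expected_superpops(map, "Hispanic", "African American"),
                  c("AFR", "AMR"))
  expect_setequal(expected_superpops(map, "Non-Hispanic", "Asian"),
                  c("ASN", "SAN"))
  expect_setequal(expected_superpops(map, "Hispanic", "White"),
                  c("AMR", "EUR"))
  expect_setequal(expected_superpops(map, "Hispanic", "Other"), "AMR")
  expect_length(expected_superpops(map, "Hispanic", "Multiracial"), 0)
  expect_length(expected_superpops(map, "Non-Hispanic", "Other"), 0)
  expect_length(expected_superpops(map, "Unknown", "Multiracial"), 0)
  expect_error(expected_superpops(map, "Hispanic", "Asian"), "not in")
  # every non-empty set is a subset of the five superpopulations
  expect_true(all(unlist(map$expected) %in%
                  c("AFR", "EUR", "ASN", "AMR", "SAN")))
})

test_that("build_crosstab counts best assignments per stratum", {
  rep_ <- self_report(c("a", "b", "c", "d"),
                      c("Non-Hispanic", "Non-Hispanic", "Non-Hispanic",
                        "Hispanic"),
                      c("White", "White", "White", "Other"))
  asn <- data.frame(sample = c("a", "b", "c", "d"),
                    best = c("EUR", "EUR", "EUR", "AMR"),
                    stringsAsFactors = FALSE)
  ct <- build_crosstab(rep_, asn)
  expect_equal(ct$EUR[ct$ethnicity == "Non-Hispanic" & ct$race == "White"], 3L)
  expect_equal(ct$AMR[ct$ethnicity == "Hispanic" & ct$race == "Other"], 1L)
  expect_equal(sum(ct$total), 4L)
  # empty inputs give an empty, total-zero table
  ct0 <- build_crosstab(rep_[0, ], asn[0, ])
  expect_equal(sum(ct0$total), 0L)
  # assignments without a report are an error
  expect_error(build_crosstab(rep_[1:3, ], asn), "without self-report")
})

test_that("crosstab on a synthetic cohort matches a brute-force tally of the truth table", {
  pan <- make_demo_panel(n_per_pop = 5, n_markers = 30, seed = 41)
  q <- simulate_query(pan$panel,
                      list(list(population = "P_EUR", n = 8),
                           list(population = "P_AFR", n = 5)), seed = 42)
  # pretend assignment recovered the truth exactly
  asn <- data.frame(sample = q$truth$sample, best = q$truth$superpopulation,
                    stringsAsFactors = FALSE)
  ct <- build_crosstab(q$report, asn)
  for (i in seq_len(nrow(ct))) {
    for (s in c("AFR", "EUR", "ASN", "AMR", "SAN")) {
      manual <- sum(q$report$ethnicity == ct$ethnicity[i] &
                    q$report$race == ct$race[i] &
                    asn$best[match(q$report$sample, asn$sample)] == s)
      expect_equal(ct[[s]][i], manual)
    }
  }
})

test_that("concordance on the published table: 601/608 evaluable calls, 98.8%", {
  ct <- published_crosstab()
  st <- concordance_stats(ct)
  expect_equal(st$n_evaluable, 608L)
  expect_equal(st$n_concordant, 601L)
  expect_equal(st$n_discordant, 7L)
  expect_equal(st$rate_pct, 98.8)
  expect_equal(st$n_concordant + st$n_discordant, st$n_evaluable)
  expect_equal(st$n_evaluable + st$no_prediction$n, sum(ct$total))
})

test_that("no-prediction subgroup of the published table: 33 samples, 11 ASN or SAN", {
  st <- concordance_stats(published_crosstab())
  expect_equal(st$no_prediction$n, 33)
  expect_equal(unname(st$no_prediction$distribution["ASN"] +
                      st$no_prediction$distribution["SAN"]), 11)
})

test_that("subgroup fractions reproduce the published ASN/SAN and Hispanic AMR counts", {
  ct <- published_crosstab()
  map <- default_expectation_map()
  evaluable <- vapply(seq_len(nrow(ct)), function(i) {
    length(expected_superpops(map, ct$ethnicity[i], ct$race[i])) > 0
  }, logical(1))
  asn_san <- subgroup_fraction(ct, evaluable, c("ASN", "SAN"))
  expect_equal(asn_san$count, 27L)
  expect_equal(asn_san$total, 608L)
  hisp <- subgroup_fraction(
    ct, data.frame(ethnicity = c("Hispanic", "Hispanic"),
                   race = c("White", "Other")), "AMR")
  expect_equal(hisp$count, 102L)
  expect_equal(hisp$total, 112L)
  none <- subgroup_fraction(ct, rep(FALSE, nrow(ct)), "AFR")
  expect_equal(none$count, 0L)
  expect_true(none$undefined)
})

test_that("all assignments inside expected sets give a 100% rate", {
  rep_ <- self_report(c("a", "b"), c("Non-Hispanic", "Hispanic"),
                      c("White", "Other"))
  asn <- data.frame(sample = c("a", "b"), best = c("EUR", "AMR"),
                    stringsAsFactors = FALSE)
  st <- concordance_stats(build_crosstab(rep_, asn))
  expect_equal(st$rate_pct, 100)
  expect_equal(st$n_discordant, 0L)
})

test_that("well-separated synthetic cohorts are nearly fully concordant end to end", {
  pan <- make_demo_panel(n_per_pop = 30, n_markers = 600,
                         fst = rep(0.12, 5), seed = 43)
  q <- simulate_query(pan$panel, lapply(
    c("P_AFR", "P_EUR", "P_ASN", "P_AMR", "P_SAN"),
    function(p) list(population = p, n = 20)), seed = 44)
  sc <- select_aims(pan$panel)
  proj <- project_joint(pan$panel$genotypes, q$genotypes,
                        marker_ids = sc$id[sc$selected], n_components = 10)
  coords <- proj$mds$coordinates
  labs <- pan$panel$superpopulation[match(
    proj$mds$samples[proj$is_reference], pan$panel$genotypes$samples)]
  m <- fit_lda(coords[proj$is_reference, ], labs)
  a <- predict(m, coords[!proj$is_reference, , drop = FALSE])
  st <- concordance_stats(build_crosstab(q$report, a))
  expect_gte(st$fraction, 0.99)
})
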