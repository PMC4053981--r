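test_that("simulation is deterministic given the seed", {
  p1 <- make_demo_panel(n_per_pop = 5, n_markers = 100, seed = 9)
  p2 <- make_demo_panel(n_per_pop = 5, n_markers = 100, seed = 9)
  expect_identical(p1$panel$genotypes$calls, p2$panel$genotypes$calls)
  expect_identical(p1$truth, p2$truth)
  p3 <- make_demo_panel(n_per_pop = 5, n_markers = 100, seed = 10)
  expect_false(identical(p1$panel$genotypes$calls, p3$panel$genotypes$calls))
})

test_that("population frequencies follow the Balding-Nichols moments", {
  # Two weakly diverged populations; the per-marker moment estimator of
  # FST from the drawn population frequencies should average to the
  # configured value within Monte-Carlo error.
  f_true <- 0.001
  pops <- list(population_spec("A", "AFR", f_true, 2),
               population_spec("B", "EUR", f_true, 2))
  pan <- simulate_panel(sim_config(pops, n_markers = 20000, seed = 5))
  pf <- attr(pan$panel, "pop_freqs")
  pbar <- colMeans(pf)
  v <- (pf[1, ] - pbar)^2 + (pf[2, ] - pbar)^2  # sample variance * (n-1)
  est <- mean(v / (pbar * (1 - pbar)))
  expect_lt(abs(est - f_true), 3e-4)

  # and at a larger FST the drawn-frequency variance matches F * p(1-p)
  pops2 <- list(population_spec("A", "AFR", 0.1, 2))
  pan2 <- simulate_panel(sim_config(pops2, n_markers = 20000,
                                    ancestral_freq_range = c(0.5, 0.5),
                                    seed = 6))
  pf2 <- attr(pan2$panel, "pop_freqs")
  expect_lt(abs(stats::var(as.vector(pf2)) - 0.1 * 0.25), 0.004)
})

test_that("LD blocks induce adjacent-marker r^2 above the pruning threshold", {
  pops <- list(population_spec("A", "EUR", 0.05, 300))
  pan <- simulate_panel(sim_config(pops, n_markers = 200,
                                   ld_block_size = 5, seed = 11))
  calls <- pan$panel$genotypes$calls
  blocks <- attr(pan$panel, "blocks")
  adj <- which(blocks[-1] == blocks[-length(blocks)])
  r2 <- vapply(adj, function(m) genotype_r2(calls[, m], calls[, m + 1]),
               numeric(1))
  expect_gt(mean(r2, na.rm = TRUE), 0.2)
  # across block boundaries markers are unlinked
  cross <- which(blocks[-1] != blocks[-length(blocks)])
  r2x <- vapply(cross, function(m) genotype_r2(calls[, m], calls[, m + 1]),
                numeric(1))
  expect_lt(mean(r2x, na.rm = TRUE), 0.05)
})

test_that("truth tables partition the generated samples", {
  pan <- make_demo_panel(n_per_pop = 7, n_markers = 50, seed = 3)
  expect_setequal(pan$truth$sample, pan$panel$genotypes$samples)
  expect_false(anyDuplicated(pan$truth$sample) > 0)
  q <- simulate_query(pan$panel,
                      list(list(population = "P_EUR", n = 4),
                           list(pop_a = "P_EUR", pop_b = "P_AFR",
                                fraction = 0.5, n = 3)),
                      seed = 2)
  expect_setequal(q$truth$sample, q$genotypes$samples)
  expect_equal(nrow(q$report), 7)
})

test_that("query self-reports follow the truth-to-category map and overrides", {
  pan <- make_demo_panel(n_per_pop = 5, n_markers = 40, seed = 8)
  q <- simulate_query(pan$panel,
                      list(list(population = "P_EUR", n = 10)), seed = 1)
  expect_true(all(q$report$ethnicity == "Non-Hispanic"))
  expect_true(all(q$report$race == "White"))
  q2 <- simulate_query(pan$panel,
                       list(list(population = "P_EUR", n = 2,
                                 ethnicity = "Non-Hispanic",
                                 race = "Multiracial")), seed = 1)
  expect_true(all(q2$report$race == "Multiracial"))
  expect_error(simulate_query(pan$panel,
                              list(list(population = "NOPE", n = 1))),
               "unknown population")
  q0 <- simulate_query(pan$panel, list(list(population = "P_EUR", n = 0)))
  expect_equal(n_samples(q0$genotypes), 0L)
  expect_equal(nrow(q0$report), 0L)
})

test_that("missingness injection matches its Bernoulli rate", {
  set.seed(1)
  g <- make_gm(matrix(sample(0:2, 10000, TRUE), nrow = 10))
  g0 <- inject_missing_and_duplicates(g, missing_rate = 0, seed = 1)
  expect_identical(g0$calls, g$calls)
  g2 <- inject_missing_and_duplicates(g, missing_rate = 0.2, seed = 1)
  frac <- mean(is.na(g2$calls))
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("planted duplicates are near-exact copies flagged in the attribute", {
  set.seed(2)
  g <- make_gm(matrix(sample(0:2, 5 * 2000, TRUE), nrow = 5))
  g2 <- inject_missing_and_duplicates(g, n_duplicates = 2, seed = 3)
  pairs <- attr(g2, "duplicate_pairs")
  expect_equal(nrow(pairs), 2)
  for (i in 1:2) {
    a <- g2$calls[pairs$original[i], ]
    b <- g2$calls[pairs$duplicate[i], ]
    expect_gt(mean(a == b), 0.98)  # <= 1% re-randomized calls
  }
})

test_that("X-chromosome simulation respects sex: hemizygous males, HWE females", {
  sexes <- c(M1 = "male", F1 = "female")
  x <- simulate_x_chromosome(sexes, 10000, freq_range = c(0.5, 0.5),
                             seed = 4)
  expect_true(all(x$markers$chrom == "X"))
  expect_equal(sum(x$calls["M1", ] == 1L), 0L)
  het <- mean(x$calls["F1", ] == 1L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)
  x0 <- simulate_x_chromosome(sexes, 0)
  expect_equal(n_markers(x0), 0L)
  expect_equal(n_samples(x0), 2L)
})

test_that("configuration invariants are enforced", {
  expect_error(population_spec("A", "AFR", 0, 5), "between 0 and 1")
  expect_error(population_spec("A", "AFR", 0.1, 0), ">= 1")
  p <- list(population_spec("A", "AFR", 0.1, 5))
  expect_error(sim_config(p, 0), ">= 1")
  expect_error(sim_config(p, 10, missing_rate = 1), "missing_rate")
  expect_error(sim_config(p, 10,
                          admixture = list(list(pop_a = "A", pop_b = "A",
                                                fraction = 1.5,
                                                n_samples = 1))),
               "fraction")
})
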