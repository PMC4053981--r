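test_that("call-rate filter uses a strict < threshold ('90% or greater' passes)", {
  calls <- matrix(0L, nrow = 3, ncol = 100)
  calls[2, 1:11] <- NA_integer_  # 89/100
  calls[3, 1:10] <- NA_integer_  # 90/100
  g <- make_gm(calls)
  cr <- call_rate_filter(g, threshold = 0.90)
  expect_equal(cr$call_rate, c(1.0, 0.89, 0.90))
  expect_equal(cr$pass, c(TRUE, FALSE, TRUE))
  g0 <- make_gm(matrix(integer(), nrow = 3, ncol = 0))
  expect_error(call_rate_filter(g0), "zero markers")
})

test_that("sex inference: hemizygous males get F = 1, HWE females F near 0", {
  sexes <- stats::setNames(rep(c("male", "female"), each = 20),
                           sprintf("S%02d", 1:40))
  x <- simulate_x_chromosome(sexes, 10000, freq_range = c(0.2, 0.8),
                             seed = 7)
  sx <- infer_sex(x)
  male <- sexes == "male"
  expect_true(all(sx$F[male] == 1))
  expect_true(all(abs(sx$F[!male]) < 0.1))
  expect_equal(sx$inferred_sex, unname(sexes))
})

test_that("sex inference excludes markers at MAF exactly the bound (strict >)", {
  # 10 samples, one marker with counted-allele frequency exactly 0.10
  calls <- matrix(c(2L, rep(0L, 9)), ncol = 1)
  x <- make_gm(calls, chrom = "X")
  expect_warning(sx <- infer_sex(x, maf_min = 0.10), "no X markers")
  expect_true(all(sx$inferred_sex == "unknown"))
  # just above the bound it is used
  calls2 <- cbind(calls, c(1L, 1L, 1L, rep(0L, 7)))
  x2 <- make_gm(calls2, chrom = "X")
  sx2 <- infer_sex(x2, maf_min = 0.10)
  expect_true(all(is.finite(sx2$F)))
})

test_that("PI_HAT is near 1 for duplicates, near 0 for unrelated, 0.5 for parent-offspring", {
  set.seed(12)
  n_mk <- 5000
  p <- runif(n_mk, 0.1, 0.9)
  unrel <- t(replicate(4, rbinom(n_mk, 2, p)))
  # parent-offspring: child gets one transmitted allele from the parent,
  # one from the population
  parent <- rbinom(n_mk, 2, p)
  child <- rbinom(n_mk, 1, parent / 2) + rbinom(n_mk, 1, p)
  calls <- rbind(unrel, unrel[1, ], parent, child)
  g <- make_gm(calls, samples = c(paste0("U", 1:4), "DUP1", "PAR", "KID"))
  ibd <- pairwise_ibd(g, freqs = p)
  pick <- function(a, b) {
    ibd$pi_hat[(ibd$sample_a == a & ibd$sample_b == b) |
               (ibd$sample_a == b & ibd$sample_b == a)]
  }
  expect_gte(pick("U1", "DUP1"), 0.95)
  expect_lt(pick("U1", "U2"), 0.1)
  expect_lt(pick("U3", "U4"), 0.1)
  expect_lt(abs(pick("PAR", "KID") - 0.5), 0.05)
  expect_true(all(ibd$pi_hat >= 0 & ibd$pi_hat <= 1))
})

test_that("PI_HAT estimates are symmetric in sample order and flag thin pairs", {
  set.seed(3)
  calls <- matrix(sample(0:2, 6 * 50, TRUE), nrow = 6)
  g <- make_gm(calls)
  ibd <- pairwise_ibd(g, min_markers = 100L)
  expect_true(all(ibd$unreliable))   # only 50 markers per pair
  g_rev <- subset_genotypes(g, samples = rev(g$samples))
  ibd_rev <- pairwise_ibd(g_rev, min_markers = 100L)
  key <- function(d) {
    k <- paste(pmin(d$sample_a, d$sample_b), pmax(d$sample_a, d$sample_b))
    stats::setNames(d$pi_hat, k)[order(k)]
  }
  expect_equal(key(ibd), key(ibd_rev), tolerance = 1e-12)
})

test_that("duplicate removal keeps the higher-call-rate member, ID tie-break, chains resolved", {
  cr <- data.frame(sample = c("A", "B", "C"),
                   call_rate = c(0.99, 0.95, 0.99),
                   pass = TRUE, stringsAsFactors = FALSE)
  ibd <- data.frame(sample_a = "A", sample_b = "B", pi_hat = 0.99,
                    stringsAsFactors = FALSE)
  expect_setequal(remove_duplicates(ibd, cr), c("A", "C"))
  # tie on call rate: lexicographically larger ID removed
  ibd2 <- data.frame(sample_a = "C", sample_b = "A", pi_hat = 0.99,
                     stringsAsFactors = FALSE)
  expect_setequal(remove_duplicates(ibd2, cr), c("A", "B"))
  # no flagged pairs: keep all
  ibd3 <- data.frame(sample_a = "A", sample_b = "B", pi_hat = 0.2,
                     stringsAsFactors = FALSE)
  expect_setequal(remove_duplicates(ibd3, cr), c("A", "B", "C"))
})

test_that("greedy duplicate removal leaves no flagged pair (brute-force check on small instances)", {
  # enumerate random <=5-sample flag graphs; after removal no kept pair
  # may remain flagged
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    ids <- LETTERS[1:n]
    pairs <- t(combn(ids, 2))
    flagged <- runif(nrow(pairs)) < 0.4
    ibd <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                      pi_hat = ifelse(flagged, 0.99, 0.1),
                      stringsAsFactors = FALSE)
    cr <- data.frame(sample = ids, call_rate = round(runif(n), 2),
                     pass = TRUE, stringsAsFactors = FALSE)
    keep <- remove_duplicates(ibd, cr)
    live <- ibd$pi_hat >= 0.95 & ibd$sample_a %in% keep &
      ibd$sample_b %in% keep
    expect_false(any(live))
    # every removal was necessary: each dropped sample had a flagged edge
    dropped <- setdiff(ids, keep)
    for (d in dropped) {
      expect_true(any(ibd$pi_hat >= 0.95 &
                      (ibd$sample_a == d | ibd$sample_b == d)))
    }
  }
})

test_that("qc_report composes the stages and reports reasons", {
  pan <- make_demo_panel(n_per_pop = 10, n_markers = 400, seed = 21)
  q <- simulate_query(pan$panel, list(list(population = "P_EUR", n = 12)),
                      seed = 1)
  g <- inject_missing_and_duplicates(q$genotypes, missing_rate = 0.02,
                                     n_duplicates = 1, seed = 2)
  # force one call-rate failure
  g$calls[3, 1:80] <- NA_integer_
  rep <- qc_report(g)
  tab <- rep$samples
  expect_equal(tab$reason[3], "low_call_rate")
  expect_equal(sum(tab$reason == "duplicate"), 1)
  expect_setequal(rep$keep, tab$sample[tab$pass])
  expect_equal(length(rep$keep), n_samples(g) - 2)
})
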