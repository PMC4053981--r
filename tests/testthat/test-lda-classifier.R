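test_that("two symmetric 1-D groups put the decision boundary at 0", {
  x <- matrix(c(-1.2, -1.0, -0.8, 0.8, 1.0, 1.2), ncol = 1)
  m <- fit_lda(x, rep(c("L", "R"), each = 3))
  at0 <- predict(m, matrix(0, ncol = 1))
  expect_equal(at0$p_best, 0.5, tolerance = 1e-12)
  left <- predict(m, matrix(-0.5, ncol = 1))
  expect_equal(left$best, "L")
})

test_that("posteriors match the MASS::lda Gaussian-discriminant oracle to 1e-8", {
  set.seed(30)
  n <- 60
  x <- rbind(matrix(rnorm(n * 3, 0), ncol = 3),
             matrix(rnorm(n * 3, 1.5), ncol = 3),
             matrix(rnorm(n * 3, -2), ncol = 3))
  labs <- rep(c("A", "B", "C"), each = n)
  m <- fit_lda(x, labs)
  grid <- matrix(rnorm(40 * 3, 0.3), ncol = 3)
  ours <- attr(predict(m, grid), "posterior")
  oracle <- MASS::lda(x, grouping = labs)
  theirs <- predict(oracle, grid)$posterior
  expect_equal(unname(ours[, c("A", "B", "C")]),
               unname(theirs[, c("A", "B", "C")]), tolerance = 1e-8)
})

test_that("the fitted model is invariant to training-sample order", {
  set.seed(31)
  x <- matrix(rnorm(40 * 2), ncol = 2)
  labs <- rep(c("A", "B"), 20)
  m1 <- fit_lda(x, labs)
  perm <- sample(40)
  m2 <- fit_lda(x[perm, ], labs[perm])
  expect_equal(m1$means, m2$means, tolerance = 1e-12)
  expect_equal(m1$cov, m2$cov, tolerance = 1e-12)
  expect_equal(m1$priors, m2$priors)
})

test_that("posteriors sum to 1 and are non-increasing in rank", {
  set.seed(32)
  x <- rbind(matrix(rnorm(20, 0), ncol = 2),
             matrix(rnorm(20, 3), ncol = 2),
             matrix(rnorm(20, -3), ncol = 2))
  labs <- rep(c("A", "B", "C"), each = 10)
  m <- fit_lda(x, labs)
  a <- predict(m, matrix(rnorm(30, 0.5), ncol = 2))
  post <- attr(a, "posterior")
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-12)
  expect_true(all(a$p_best >= a$p_second & a$p_second >= a$p_third))
})

test_that("a query at a well-separated centroid gets posterior > 0.99; equidistant queries tie", {
  set.seed(33)
  x <- rbind(matrix(rnorm(40, -5, 0.5), ncol = 2),
             matrix(rnorm(40, 5, 0.5), ncol = 2))
  labs <- rep(c("A", "B"), each = 20)
  m <- fit_lda(x, labs)
  m$priors <- c(0.5, 0.5)  # equal priors for the symmetry check
  at_a <- predict(m, m$means["A", , drop = FALSE])
  expect_equal(at_a$best, "A")
  expect_gt(at_a$p_best, 0.99)
  mid <- predict(m, matrix(colMeans(m$means), ncol = 2))
  expect_equal(mid$p_best, mid$p_second, tolerance = 1e-12)
})

test_that("with equal priors and spherical covariance prediction is nearest-centroid", {
  set.seed(34)
  means <- matrix(c(0, 0, 4, 0, 0, 4), ncol = 2, byrow = TRUE,
                  dimnames = list(c("A", "B", "C"), NULL))
  m <- structure(list(groups = c("A", "B", "C"), means = means,
                      cov = diag(2), priors = rep(1 / 3, 3)),
                 class = "discriminant_model")
  q <- matrix(rnorm(100, 1, 3), ncol = 2)
  a <- predict(m, q)
  d2 <- sapply(1:3, function(k) colSums((t(q) - means[k, ])^2))
  expect_equal(a$best, c("A", "B", "C")[apply(d2, 1, which.min)])
})

test_that("training data is classified perfectly when groups are separable with margin", {
  set.seed(35)
  x <- rbind(matrix(c(0:9, 0:9), ncol = 2),
             matrix(c(0:9 + 30, 0:9), ncol = 2))
  x <- x + matrix(stats::rnorm(40, 0, 0.1), ncol = 2)  # break exact ties
  labs <- rep(c("A", "B"), each = 10)
  m <- fit_lda(x, labs)
  a <- predict(m, x)
  expect_equal(a$best, labs)
})

test_that("fit and predict validate their inputs", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_lda(x, rep("A", 10)), "at least 2 groups")
  expect_error(fit_lda(x, c("A", rep("B", 9))), "singleton")
  m <- fit_lda(x, rep(c("A", "B"), each = 5))
  expect_error(predict(m, matrix(0, 1, 3)), "dimensions")
})

test_that("rank_match finds the rank of the expected set, flagging no-prediction", {
  post <- rbind(c(A = 0.7, B = 0.2, C = 0.1),
                c(A = 0.1, B = 0.3, C = 0.6),
                c(A = 0.5, B = 0.4, C = 0.1))
  a <- data.frame(sample = c("s1", "s2", "s3"),
                  best = c("A", "C", "A"), stringsAsFactors = FALSE)
  attr(a, "posterior") <- post
  class(a) <- c("assignments", "data.frame")
  rm_ <- rank_match(a, list("A", c("A", "B"), character(0)))
  expect_equal(rm_$match_rank, c(1L, 2L, NA_integer_))
  expect_equal(rm_$no_prediction, c(FALSE, FALSE, TRUE))
  # one shared expected set for all samples
  rm2 <- rank_match(a, "C")
  expect_equal(rm2$match_rank, c(3L, 1L, 3L))
})

test_that("admixed queries match their expected group within the top two ranks", {
  pan <- make_demo_panel(n_per_pop = 40, n_markers = 800,
                         fst = rep(0.1, 5), seed = 36)
  q <- simulate_query(pan$panel,
                      list(list(pop_a = "P_EUR", pop_b = "P_AFR",
                                fraction = 0.5, n = 30)), seed = 37)
  sc <- select_aims(pan$panel)
  proj <- project_joint(pan$panel$genotypes, q$genotypes,
                        marker_ids = sc$id[sc$selected], n_components = 10)
  coords <- proj$mds$coordinates
  labs <- pan$panel$superpopulation[match(
    proj$mds$samples[proj$is_reference], pan$panel$genotypes$samples)]
  m <- fit_lda(coords[proj$is_reference, ], labs)
  a <- predict(m, coords[!proj$is_reference, , drop = FALSE])
  rm_ <- rank_match(a, "EUR")
  expect_gte(mean(rm_$match_rank <= 2), 0.9)
  # and the admixed centroid lies between the two parental centroids on dim 1
  cent <- tapply(coords[proj$is_reference, 1], labs, mean)
  adm <- mean(coords[!proj$is_reference, 1])
  expect_true(adm > min(cent["AFR"], cent["EUR"]) &&
              adm < max(cent["AFR"], cent["EUR"]))
})

test_that("population-level posteriors roll up to superpopulations", {
  post <- rbind(c(P1 = 0.3, P2 = 0.3, Q1 = 0.4))
  a <- data.frame(sample = "s1", best = "Q1", stringsAsFactors = FALSE)
  attr(a, "posterior") <- post
  class(a) <- c("assignments", "data.frame")
  r <- rollup_assignments(a, c(P1 = "SUP1", P2 = "SUP1", Q1 = "SUP2"))
  expect_equal(r$best, "SUP1")
  expect_equal(r$p_best, 0.6, tolerance = 1e-12)
})
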