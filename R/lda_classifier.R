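# Linear discriminant classification of query samples in MDS space:
# Gaussian model with per-group means, a shared pooled within-group
# covariance, and priors proportional to reference group sizes. The
# closed-form Gaussian posterior is the contract.

#' Fit a linear discriminant model on reference coordinates
#'
#' Group means are the centroids; the shared covariance is the pooled
#' within-group sample covariance (denominator N - K); priors are
#' proportional to group sizes. If the pooled covariance has condition
#' number above 1e8 a ridge `eps * trace / D` is added to the diagonal so
#' tiny synthetic panels stay invertible.
#'
#' @param coords numeric matrix (reference samples x D, D >= 1), e.g. the
#'   reference rows of an [classical_mds()] result.
#' @param labels character vector of group labels, one per row; every
#'   group needs at least 2 samples.
#' @param ridge_eps ridge multiplier applied when ill-conditioned; default
#'   1e-6.
#' @return An object of class `discriminant_model`: `groups`, `means`
#'   (groups x D), `cov` (D x D), `priors`.
#' @export
fit_lda <- function(coords, labels, ridge_eps = 1e-6) {
  coords <- as.matrix(coords)
  if (ncol(coords) < 1) stop("need at least one coordinate dimension")
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  counts <- table(factor(labels, levels = groups))
  if (any(counts < 2)) {
    stop("singleton group(s): ", paste(groups[counts < 2], collapse = ", "))
  }
  d <- ncol(coords)
  means <- matrix(NA_real_, length(groups), d,
                  dimnames = list(groups, colnames(coords)))
  s <- matrix(0, d, d)
  for (k in seq_along(groups)) {
    xk <- coords[labels == groups[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    xc <- sweep(xk, 2, means[k, ])
    s <- s + crossprod(xc)
  }
  s <- s / (nrow(coords) - length(groups))
  if (kappa(s, exact = TRUE) > 1e8) {
    s <- s + diag(ridge_eps * sum(diag(s)) / d + 1e-12, d)
  }
  structure(list(groups = groups, means = means, cov = s,
                 priors = as.numeric(counts) / length(labels)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("discriminant_model: %d groups (%s), %d dimensions\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              ncol(x$means)))
  invisible(x)
}

#' Classify query coordinates
#'
#' Posterior for group k is proportional to
#' `prior_k * exp(-Mahalanobis^2 / 2)` under the shared covariance,
#' normalized to sum to 1. Groups are ranked by posterior (ties broken by
#' group order), and the top three are unpacked into columns.
#'
#' @param object a `discriminant_model` from [fit_lda()].
#' @param coords query samples x D matrix in the same MDS space (joint
#'   projection); row names become sample IDs.
#' @param ... unused.
#' @return A data.frame of class `assignments`: `sample`, `best`,
#'   `p_best`, `second`, `p_second`, `third`, `p_third`. The full
#'   posterior matrix (samples x groups) is in the `posterior` attribute.
#' @export
predict.discriminant_model <- function(object, coords, ...) {
  coords <- as.matrix(coords)
  if (ncol(coords) != ncol(object$means)) {
    stop(sprintf("query has %d dimensions, model expects %d",
                 ncol(coords), ncol(object$means)))
  }
  n <- nrow(coords)
  k <- length(object$groups)
  logpost <- matrix(NA_real_, n, k, dimnames = list(NULL, object$groups))
  for (j in seq_len(k)) {
    q <- stats::mahalanobis(coords, object$means[j, ], object$cov)
    logpost[, j] <- log(object$priors[j]) - q / 2
  }
  m <- apply(logpost, 1, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  rownames(post) <- rownames(coords) %||% as.character(seq_len(n))

  ord <- t(apply(post, 1, order, decreasing = TRUE))
  pick <- function(r) object$groups[ord[, r]]
  pickp <- function(r) post[cbind(seq_len(n), ord[, r])]
  third <- if (k >= 3) pick(3) else rep(NA_character_, n)
  p_third <- if (k >= 3) pickp(3) else rep(NA_real_, n)
  out <- data.frame(sample = rownames(post),
                    best = pick(1), p_best = pickp(1),
                    second = pick(2), p_second = pickp(2),
                    third = third, p_third = p_third,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  class(out) <- c("assignments", "data.frame")
  out
}

#' Rank at which an expected group set is first matched
#'
#' For each sample, walks its posterior-ranked group list and reports the
#' rank (1 = best) of the first group contained in the expected set.
#' Expected sets may differ per sample and may be empty ("no prediction"),
#' in which case the rank is `NA` and the sample is flagged.
#'
#' @param assignments an `assignments` object from
#'   [predict.discriminant_model()].
#' @param expected a character vector (one set for all samples) or a list
#'   of character vectors, one per sample; `character(0)` means no
#'   prediction is expected.
#' @return data.frame: `sample`, `match_rank`, `no_prediction`.
#' @export
rank_match <- function(assignments, expected) {
  post <- attr(assignments, "posterior")
  groups <- colnames(post)
  n <- nrow(post)
  if (!is.list(expected)) expected <- rep(list(expected), n)
  stopifnot(length(expected) == n)
  rank_of <- function(i) {
    exp_i <- expected[[i]]
    if (length(exp_i) == 0) return(NA_integer_)
    ord <- order(post[i, ], decreasing = TRUE)
    hit <- which(groups[ord] %in% exp_i)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  mr <- vapply(seq_len(n), rank_of, integer(1))
  data.frame(sample = assignments$sample, match_rank = mr,
             no_prediction = lengths(expected) == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Roll population-level assignments up to superpopulations
#'
#' Sums posterior mass over the populations of each superpopulation and
#' re-ranks, for population-level analyses reported at superpopulation
#' resolution.
#'
#' @param assignments an `assignments` object over population labels.
#' @param pop_to_super named character vector mapping population to
#'   superpopulation.
#' @return An `assignments` object over superpopulation labels.
#' @export
rollup_assignments <- function(assignments, pop_to_super) {
  post <- attr(assignments, "posterior")
  sup <- pop_to_super[colnames(post)]
  if (anyNA(sup)) stop("population(s) missing from pop_to_super map")
  sups <- sort(unique(unname(sup)))
  agg <- sapply(sups, function(s) {
    rowSums(post[, sup == s, drop = FALSE])
  })
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(post), sups))
  n <- nrow(agg); k <- ncol(agg)
  ord <- t(apply(agg, 1, order, decreasing = TRUE))
  pick <- function(r) sups[ord[, r]]
  pickp <- function(r) agg[cbind(seq_len(n), ord[, r])]
  third <- if (k >= 3) pick(3) else rep(NA_character_, n)
  p_third <- if (k >= 3) pickp(3) else rep(NA_real_, n)
  out <- data.frame(sample = assignments$sample,
                    best = pick(1), p_best = pickp(1),
                    second = pick(2), p_second = pickp(2),
                    third = third, p_third = p_third,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "posterior") <- agg
  class(out) <- c("assignments", "data.frame")
  out
}
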