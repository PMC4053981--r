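# Joint projection of reference and query genotypes: identity-by-state
# distance and classical (metric) multidimensional scaling. Reference and
# query samples enter one distance matrix together, so no out-of-sample
# projection step is needed.

#' Identity-by-state distance matrix
#'
#' For each sample pair, IBS at a marker is the number of shared alleles
#' (`2 - |dosage_i - dosage_j|`, in 0..2), averaged over markers non-missing
#' in both samples:
#' `distance(i, j) = 1 - sum_m ibs_m / (2 * n_complete)`.
#' Symmetric, zero diagonal, values in \[0, 1\].
#'
#' @param g a [genotype_matrix()] with at least 2 samples and 1 marker.
#' @return A dense symmetric matrix with sample IDs as dimnames.
#' @export
ibs_distance <- function(g) {
  if (n_samples(g) < 2) stop("need at least 2 samples")
  if (n_markers(g) < 1) stop("need at least 1 marker")
  calls <- g$calls
  A <- list()
  for (d in 0:2) {
    m <- calls == d
    m[is.na(m)] <- FALSE
    A[[d + 1L]] <- m * 1
  }
  obs <- (!is.na(calls)) * 1
  n_cmp <- obs %*% t(obs)
  if (any(n_cmp == 0)) {
    idx <- which(n_cmp == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no complete markers",
                 g$samples[idx[1]], g$samples[idx[2]]))
  }
  # sum over markers of |dosage_i - dosage_j| via dosage-class cross counts
  d01 <- A[[1]] %*% t(A[[2]]); d02 <- A[[1]] %*% t(A[[3]])
  d12 <- A[[2]] %*% t(A[[3]])
  sum_abs <- d01 + t(d01) + 2 * (d02 + t(d02)) + d12 + t(d12)
  d <- sum_abs / (2 * n_cmp)
  diag(d) <- 0
  dimnames(d) <- list(g$samples, g$samples)
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` for the leading positive eigenvalues.
#' Components with non-positive eigenvalues are dropped, so fewer than
#' `n_components` dimensions may be returned (with a warning). Sign
#' convention: within each column the entry of largest magnitude is made
#' positive, so runs are reproducible.
#'
#' @param dist symmetric distance matrix with zero diagonal.
#' @param n_components maximum dimensions to return; default 20.
#' @return An object of class `mds_result`: `samples`, `coordinates`
#'   (samples x D), `eigenvalues` (non-increasing, length D).
#' @export
classical_mds <- function(dist, n_components = 20L) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(dist)
  samples <- rownames(dist) %||% as.character(seq_len(n))
  d2 <- dist^2
  # double-centering: B = -1/2 (I - 11'/n) D^2 (I - 11'/n)
  rm_ <- rowMeans(d2); gm <- mean(d2)
  b <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen(b, symmetric = TRUE)
  pos <- e$values > max(e$values[1], 0) * 1e-12 & e$values > 0
  k <- min(sum(pos), n_components)
  if (k < n_components) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    sum(pos), k))
  }
  if (k == 0) stop("no positive eigenvalues; degenerate distance matrix")
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals), `*`)
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(samples, paste0("dim", seq_len(k)))
  structure(list(samples = samples, coordinates = coords,
                 eigenvalues = vals),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result: %d samples x %d dimensions; leading eigenvalues %s\n",
              length(x$samples), ncol(x$coordinates),
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Project reference and query genotypes jointly
#'
#' Convenience wrapper: stacks reference and query samples over the marker
#' subset (typically the selected AIMs), computes the IBS distance matrix
#' over all samples together, and runs classical MDS.
#'
#' @param reference,query `genotype_matrix` objects over identical markers.
#' @param marker_ids optional character vector restricting to a marker
#'   subset (e.g. `id` of selected rows from [select_aims()]).
#' @param n_components passed to [classical_mds()].
#' @return list: `mds` (an `mds_result`), `is_reference` (logical per row).
#' @export
project_joint <- function(reference, query, marker_ids = NULL,
                          n_components = 20L) {
  if (!is.null(marker_ids)) {
    reference <- subset_genotypes(reference, markers = marker_ids)
    query <- subset_genotypes(query, markers = marker_ids)
  }
  all_g <- bind_samples(reference, query)
  mds <- classical_mds(ibs_distance(all_g), n_components)
  list(mds = mds,
       is_reference = mds$samples %in% reference$samples)
}
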