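# Sample quality control: call-rate filtering, sex inference from
# X-chromosome homozygosity, duplicate detection via method-of-moments IBD.

#' Per-sample call-rate filter
#'
#' Call rate is the fraction of markers with a non-missing call. A sample
#' fails iff its call rate is strictly below `threshold` ("90% or greater"
#' passes at the default).
#'
#' @param g a [genotype_matrix()].
#' @param threshold minimum call rate to pass; default 0.90.
#' @return data.frame: `sample`, `call_rate`, `pass`.
#' @export
call_rate_filter <- function(g, threshold = 0.90) {
  if (n_markers(g) == 0L) stop("genotype matrix has zero markers")
  cr <- rowMeans(!is.na(g$calls))
  data.frame(sample = g$samples, call_rate = cr, pass = cr >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Infer sample sex from X-chromosome homozygosity
#'
#' Restricts to X markers with minor allele frequency strictly above
#' `maf_min` (frequencies estimated from the cohort unless supplied), then
#' computes per sample the inbreeding-style homozygosity excess
#' `F = (O_hom - E_hom) / (n_used - E_hom)`, where `E_hom` sums
#' `1 - 2 p_j (1 - p_j)` over the sample's non-missing used markers.
#' Hemizygous males have no heterozygous calls, so F = 1; diploid females
#' under Hardy-Weinberg have F near 0. Calls male if `F > 0.8`, female if
#' `F < 0.2`, otherwise unknown.
#'
#' @param x a [genotype_matrix()] restricted to chromosome X.
#' @param maf_min strict lower MAF bound for usable markers; default 0.10.
#' @param freqs optional per-marker counted-allele frequencies; estimated
#'   from `x` when `NULL`.
#' @return data.frame: `sample`, `F`, `inferred_sex`.
#' @export
infer_sex <- function(x, maf_min = 0.10, freqs = NULL) {
  if (n_markers(x) > 0L && !all(x$markers$chrom == "X")) {
    stop("infer_sex expects markers restricted to chromosome X")
  }
  p <- freqs %||% as.vector(group_allele_freqs(
    x$calls, rep("all", n_samples(x))))
  maf <- pmin(p, 1 - p)
  use <- !is.na(maf) & maf > maf_min
  if (!any(use)) {
    warning("no X markers pass the MAF filter; sex unknown for all samples")
    return(data.frame(sample = x$samples, F = NA_real_,
                      inferred_sex = "unknown", row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  calls <- x$calls[, use, drop = FALSE]
  p <- p[use]
  obs <- !is.na(calls)
  n_used <- rowSums(obs)
  o_hom <- rowSums(calls == 0L | calls == 2L, na.rm = TRUE)
  e_marker <- 1 - 2 * p * (1 - p)
  e_hom <- obs %*% e_marker
  f <- as.vector((o_hom - e_hom) / (n_used - e_hom))
  f[n_used == 0] <- NA_real_
  sex <- rep("unknown", length(f))
  sex[!is.na(f) & f > 0.8] <- "male"
  sex[!is.na(f) & f < 0.2] <- "female"
  data.frame(sample = x$samples, F = f, inferred_sex = sex,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise identity-by-descent estimates (PI_HAT)
#'
#' PLINK-style method-of-moments estimator. For each pair, observed
#' identity-by-state (IBS) 0/1/2 counts over markers non-missing in both
#' samples are combined with allele-frequency-based expected
#' IBS-given-IBD probabilities to solve for P(IBD = 0), P(IBD = 1),
#' P(IBD = 2); the solution is clamped to the probability simplex and
#' `PI_HAT = P(IBD = 2) + P(IBD = 1) / 2`. Duplicated samples give PI_HAT
#' near 1, parent-offspring pairs near 0.5, unrelated pairs near 0.
#'
#' @param g a [genotype_matrix()] of autosomal markers.
#' @param freqs optional per-marker counted-allele frequencies in (0, 1);
#'   estimated from the cohort when `NULL`.
#' @param min_markers pairs with fewer usable markers are flagged
#'   `unreliable`; default 100.
#' @return data.frame: `sample_a`, `sample_b`, `pi_hat`, `n_markers`,
#'   `unreliable`, for all unordered pairs.
#' @export
pairwise_ibd <- function(g, freqs = NULL, min_markers = 100L) {
  if (any(g$markers$chrom == "X")) stop("pairwise_ibd expects autosomal markers")
  p <- freqs %||% as.vector(group_allele_freqs(
    g$calls, rep("all", n_samples(g))))
  # Markers need both alleles segregating for the IBS expectations to be
  # informative; monomorphic ones contribute nothing and are dropped.
  use <- !is.na(p) & p > 0 & p < 1
  calls <- g$calls[, use, drop = FALSE]
  p <- p[use]
  q <- 1 - p
  n <- nrow(calls)
  if (n < 2L) stop("need at least two samples")

  # Indicator matrices by dosage; matrix products give per-pair counts of
  # each ordered dosage combination over pairwise-complete markers.
  A <- list()
  for (d in 0:2) {
    m <- calls == d
    m[is.na(m)] <- FALSE
    A[[d + 1L]] <- m * 1
  }
  obs <- (!is.na(calls)) * 1
  # |d_i - d_j| = 2  <=>  IBS0 ; = 1 <=> IBS1
  ibs0 <- A[[1]] %*% t(A[[3]]); ibs0 <- ibs0 + t(ibs0)
  ibs1 <- A[[1]] %*% t(A[[2]]) + A[[2]] %*% t(A[[3]])
  ibs1 <- ibs1 + t(ibs1)
  n_cmp <- obs %*% t(obs)

  # Expected IBS-class probabilities given IBD state, summed over the
  # markers each pair actually shares: E*[i,j] = sum_m w_m obs_im obs_jm.
  pair_sum <- function(w) obs %*% (w * t(obs))
  e0_z0 <- pair_sum(2 * p^2 * q^2)
  e1_z0 <- pair_sum(4 * p^3 * q + 4 * p * q^3)
  e1_z1 <- pair_sum(2 * p^2 * q + 2 * p * q^2)
  e2_z0 <- n_cmp - e0_z0 - e1_z0
  e2_z1 <- n_cmp - e1_z1

  z0 <- ibs0 / e0_z0
  z1 <- (ibs1 - z0 * e1_z0) / e1_z1
  n2 <- n_cmp - ibs0 - ibs1
  z2 <- (n2 - z0 * e2_z0 - z1 * e2_z1) / n_cmp

  idx <- which(upper.tri(z0), arr.ind = TRUE)
  z <- cbind(z0[idx], z1[idx], z2[idx])
  # Clamp to the simplex: negatives to 0, then renormalize.
  z[z < 0] <- 0
  z[z > 1] <- 1
  tot <- rowSums(z)
  bad <- tot == 0
  if (any(bad)) z[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
  z <- z / rowSums(z)
  pi_hat <- z[, 3] + z[, 2] / 2
  nm <- n_cmp[idx]
  data.frame(sample_a = g$samples[idx[, 2]], sample_b = g$samples[idx[, 1]],
             pi_hat = pi_hat, n_markers = nm,
             unreliable = nm < min_markers,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Resolve duplicate pairs into a keep-list
#'
#' From each pair with `pi_hat >= pi_hat_threshold`, greedily removes the
#' member with the lower call rate (ties: the lexicographically larger ID
#' is removed), repeating until no flagged pair remains among kept samples.
#'
#' @param ibd data.frame from [pairwise_ibd()].
#' @param call_rates data.frame from [call_rate_filter()].
#' @param pi_hat_threshold flagging threshold; default 0.95
#'   ("approximately 1").
#' @return character vector of sample IDs to keep.
#' @export
remove_duplicates <- function(ibd, call_rates, pi_hat_threshold = 0.95) {
  keep <- call_rates$sample
  cr <- stats::setNames(call_rates$call_rate, call_rates$sample)
  flagged <- ibd[ibd$pi_hat >= pi_hat_threshold, , drop = FALSE]
  repeat {
    live <- flagged$sample_a %in% keep & flagged$sample_b %in% keep
    if (!any(live)) break
    pair <- flagged[which(live)[1], ]
    a <- pair$sample_a; b <- pair$sample_b
    drop <- if (cr[[a]] < cr[[b]]) a
            else if (cr[[b]] < cr[[a]]) b
            else max(a, b)
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Full sample-QC report
#'
#' Runs the three QC stages in order: call-rate filter, sex inference (when
#' X genotypes are provided), then duplicate detection among samples that
#' passed the call-rate filter (allele frequencies are computed after
#' removing call-rate failures). Fails are exactly the call-rate failures
#' plus the dropped member of each duplicate pair.
#'
#' @param g autosomal [genotype_matrix()].
#' @param x_genotypes optional X-chromosome `genotype_matrix` for the same
#'   samples.
#' @param reported_sex optional named vector of reported sexes; mismatches
#'   with inferred sex are flagged in the report.
#' @param call_rate_min,maf_min,pi_hat_max thresholds (defaults 0.90, 0.10,
#'   0.95).
#' @return list of class `qc_report`: `samples` (per-sample table with
#'   `call_rate`, `F`, `inferred_sex`, `sex_mismatch`, `pass`, `reason`),
#'   `ibd` (pairwise table), `keep` (IDs passing all filters).
#' @export
qc_report <- function(g, x_genotypes = NULL, reported_sex = NULL,
                      call_rate_min = 0.90, maf_min = 0.10,
                      pi_hat_max = 0.95) {
  cr <- call_rate_filter(g, call_rate_min)
  tab <- data.frame(sample = cr$sample, call_rate = cr$call_rate,
                    F = NA_real_, inferred_sex = "unknown",
                    sex_mismatch = FALSE,
                    pass = cr$pass, reason = ifelse(cr$pass, "", "low_call_rate"),
                    stringsAsFactors = FALSE)
  if (!is.null(x_genotypes)) {
    sx <- infer_sex(x_genotypes, maf_min)
    m <- match(tab$sample, sx$sample)
    tab$F <- sx$F[m]
    tab$inferred_sex <- ifelse(is.na(m), "unknown", sx$inferred_sex[m])
    if (!is.null(reported_sex)) {
      rep_sex <- reported_sex[tab$sample]
      tab$sex_mismatch <- !is.na(rep_sex) & rep_sex != "unknown" &
        tab$inferred_sex != "unknown" & rep_sex != tab$inferred_sex
    }
  }
  passing <- tab$sample[tab$pass]
  ibd <- NULL
  if (length(passing) >= 2L) {
    g_pass <- subset_genotypes(g, samples = passing)
    ibd <- pairwise_ibd(g_pass)
    keep <- remove_duplicates(ibd, cr[cr$pass, , drop = FALSE], pi_hat_max)
    dup_drop <- setdiff(passing, keep)
    tab$pass[tab$sample %in% dup_drop] <- FALSE
    tab$reason[tab$sample %in% dup_drop] <- "duplicate"
  }
  structure(list(samples = tab, ibd = ibd, keep = tab$sample[tab$pass]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d pass (%d low call rate, %d duplicate)\n",
              nrow(x$samples), sum(x$samples$pass),
              sum(x$samples$reason == "low_call_rate"),
              sum(x$samples$reason == "duplicate")))
  invisible(x)
}
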