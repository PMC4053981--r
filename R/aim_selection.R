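# Ancestry-informative marker selection: rank markers by informativeness
# for assignment across labelled groups, then greedily keep an LD-pruned
# subset (r^2 < 0.2 within 1 Mb against previously chosen markers).

#' Informativeness for assignment of a biallelic marker
#'
#' Entropy-based statistic measuring how well a marker's allele frequencies
#' distinguish K predefined groups:
#' `I_n = sum over alleles [ -pbar ln(pbar) + (1/K) sum_i p_i ln(p_i) ]`,
#' with `pbar` the unweighted mean frequency across groups and
#' `0 ln 0 = 0`. It is 0 when all groups share the same frequency and at
#' most `ln K` (attained only at disjoint fixation patterns). Natural-log
#' units (nats); only the ordering matters downstream.
#'
#' @param freqs counted-allele frequencies: a numeric vector (one per
#'   group) for a single marker, or a groups x markers matrix. `NA` entries
#'   (groups with no calls at a marker) are dropped for that marker; if
#'   fewer than 2 groups remain the marker scores `NA`.
#' @return numeric; one value per marker.
#' @export
informativeness <- function(freqs) {
  if (is.matrix(freqs)) {
    if (nrow(freqs) < 2) stop("need at least 2 groups")
    return(apply(freqs, 2, informativeness_one))
  }
  informativeness_one(freqs)
}

informativeness_one <- function(p) {
  if (length(p) < 2) stop("need at least 2 groups")
  p <- p[!is.na(p)]
  if (length(p) < 2) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  total <- 0
  for (pa in list(p, 1 - p)) {
    pbar <- mean(pa)
    total <- total - xlx(pbar) + mean(xlx(pa))
  }
  # Clamp tiny negative rounding error; the statistic is >= 0.
  max(total, 0)
}

#' Composite genotype r-squared between two markers
#'
#' Squared Pearson correlation of the two dosage vectors over samples with
#' both calls present. This is the genotype (composite) r^2 suitable for
#' unphased data, as used by PLINK-style LD pruning. A monomorphic marker
#' is defined to have r^2 = 0 with anything (it never blocks selection);
#' fewer than 2 complete pairs also gives 0, with a warning.
#'
#' @param a,b integer dosage vectors of equal length (`NA` = missing).
#' @return r^2 in \[0, 1\].
#' @export
genotype_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) {
    warning("fewer than 2 pairwise-complete samples; r^2 treated as 0")
    return(0)
  }
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(0)
  stats::cor(a, b)^2
}

#' Select ancestry-informative markers by greedy LD-pruned ranking
#'
#' Scores every marker's informativeness for assignment over the panel's
#' group labels, then iterates markers in decreasing informativeness (ties
#' broken by chromosome, then position) and accepts a marker iff its
#' genotype r^2 is strictly below `r2_max` against every already-accepted
#' marker within `window_bp` (inclusive) on the same chromosome. All
#' markers with positive informativeness are kept unless `max_markers`
#' caps the list. No minor-allele-frequency filter is applied.
#'
#' @param panel a [reference_panel()].
#' @param group_field `"superpopulation"` (default) or `"population"`: the
#'   label set over which informativeness is computed.
#' @param r2_max strict LD threshold; default 0.2.
#' @param window_bp LD window in base pairs, inclusive; default 1e6 (1 Mb).
#' @param max_markers optional cap on the number of selected markers.
#' @return data.frame of marker scores in decreasing-informativeness order:
#'   `id`, `chrom`, `pos`, `informativeness`, `selected`, `rank`, plus one
#'   `freq_<group>` column per group.
#' @export
select_aims <- function(panel, group_field = c("superpopulation", "population"),
                        r2_max = 0.2, window_bp = 1000000L,
                        max_markers = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  group_field <- match.arg(group_field)
  groups <- panel[[group_field]]
  if (anyNA(groups) || any(groups == "")) stop("panel has unlabeled samples")
  g <- panel$genotypes
  freqs <- group_allele_freqs(g$calls, groups)
  info <- informativeness(freqs)
  info[is.na(info)] <- 0

  mk <- g$markers
  chrom_num <- match(mk$chrom, c(as.character(1:22), "X"))
  ord <- order(-info, chrom_num, mk$pos)
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)

  selected <- logical(nrow(mk))
  n_sel <- 0L
  cap <- max_markers %||% Inf
  for (j in ord) {
    if (n_sel >= cap) break
    if (info[j] <= 0) break  # ordered, so all remaining are uninformative
    near <- which(selected & mk$chrom == mk$chrom[j] &
                  abs(mk$pos - mk$pos[j]) <= window_bp)
    ok <- TRUE
    if (length(near) > 0) {
      r2 <- suppressWarnings(
        vapply(near, function(k) genotype_r2(g$calls[, j], g$calls[, k]),
               numeric(1)))
      ok <- all(r2 < r2_max)
    }
    if (ok) {
      selected[j] <- TRUE
      n_sel <- n_sel + 1L
    }
  }
  out <- data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos,
                    informativeness = info, selected = selected,
                    rank = rank, stringsAsFactors = FALSE)
  fr <- as.data.frame(t(freqs))
  names(fr) <- paste0("freq_", rownames(freqs))
  out <- cbind(out, fr)
  out[ord, , drop = FALSE]
}
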