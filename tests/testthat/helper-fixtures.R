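# Shared fixture builders and independent oracles, all generated in code.

# Small genotype matrix with evenly spaced markers on one chromosome.
make_gm <- function(calls, chrom = "1", spacing = 50000L,
                    samples = sprintf("S%02d", seq_len(nrow(calls)))) {
  n_mk <- ncol(calls)
  mk <- marker_info(id = sprintf("m%03d", seq_len(n_mk)),
                    chrom = rep(chrom, n_mk),
                    pos = 1L + spacing * (seq_len(n_mk) - 1L),
                    counted = rep("A", n_mk), other = rep("G", n_mk))
  genotype_matrix(calls, mk, samples)
}

# A small five-population reference panel (one population per
# superpopulation), shared by several stochastic tests.
make_demo_panel <- function(n_per_pop = 40, n_markers = 1500,
                            fst = c(0.12, 0.10, 0.12, 0.08, 0.10),
                            ld_block_size = 1L, seed = 42) {
  sups <- c("AFR", "EUR", "ASN", "AMR", "SAN")
  pops <- lapply(seq_along(sups), function(i) {
    population_spec(paste0("P_", sups[i]), sups[i], fst[i], n_per_pop)
  })
  simulate_panel(sim_config(pops, n_markers = n_markers,
                            ld_block_size = ld_block_size, seed = seed))
}

# Independent double-loop IBS distance oracle (per-marker tally).
oracle_ibs_distance <- function(calls) {
  n <- nrow(calls)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ibs <- 0; n_cmp <- 0
    for (m in seq_len(ncol(calls))) {
      a <- calls[i, m]; b <- calls[j, m]
      if (!is.na(a) && !is.na(b)) {
        ibs <- ibs + (2 - abs(a - b))
        n_cmp <- n_cmp + 1
      }
    }
    d[i, j] <- 1 - ibs / (2 * n_cmp)
  }
  d
}

# Independent brute-force greedy AIM selection oracle: ranks by
# informativeness (ties by chromosome then position) and re-checks every
# accepted marker in the window with a from-scratch correlation.
oracle_select_aims <- function(panel, group_field = "superpopulation",
                               r2_max = 0.2, window_bp = 1e6) {
  g <- panel$genotypes
  groups <- panel[[group_field]]
  n_mk <- n_markers(g)
  info <- numeric(n_mk)
  for (j in seq_len(n_mk)) {
    p <- tapply(g$calls[, j], groups,
                function(v) mean(v, na.rm = TRUE) / 2)
    p <- p[!is.na(p)]
    xlx <- function(x) ifelse(x > 0, x * log(x), 0)
    tot <- 0
    for (pa in list(p, 1 - p)) tot <- tot - xlx(mean(pa)) + mean(xlx(pa))
    info[j] <- max(tot, 0)
  }
  chrom_rank <- match(g$markers$chrom, c(as.character(1:22), "X"))
  ord <- order(-info, chrom_rank, g$markers$pos)
  sel <- integer(0)
  for (j in ord) {
    if (info[j] <= 0) next
    ok <- TRUE
    for (k in sel) {
      if (g$markers$chrom[k] == g$markers$chrom[j] &&
          abs(g$markers$pos[k] - g$markers$pos[j]) <= window_bp) {
        cc <- stats::cor(g$calls[, j], g$calls[, k],
                         use = "pairwise.complete.obs")
        if (is.na(cc)) cc <- 0
        if (cc^2 >= r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) sel <- c(sel, j)
  }
  sort(g$markers$id[sel])
}

# Procrustes residual after optimal rigid alignment (rotation/reflection +
# translation + scale-free), via SVD. Independent of vegan.
procrustes_residual <- function(x, y) {
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  r <- s$u %*% t(s$v)
  sum((xc - yc %*% r)^2)
}
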