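# Structured-genotype simulator: Balding-Nichols populations with tunable
# FST, optional two-way admixture, local LD via block-haplotype copying,
# genotype missingness, X-chromosome genotypes consistent with sex, and
# planted duplicate samples. Gives every downstream stage a ground truth in
# place of controlled-access reference/query data.

#' Describe one simulated population
#'
#' @param name population label (e.g. `"POP_EUR"`).
#' @param superpopulation superpopulation label the population rolls up to.
#' @param fst Balding-Nichols divergence parameter, strictly in (0, 1):
#'   the expected variance of the population allele frequency around the
#'   ancestral frequency `p` is `fst * p * (1 - p)`.
#' @param n_samples number of reference samples to draw (>= 1).
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, superpopulation, fst, n_samples) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(superpopulation), length(superpopulation) == 1)
  if (!(fst > 0 && fst < 1)) stop("fst must be strictly between 0 and 1")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(list(name = name, superpopulation = superpopulation,
                 fst = fst, n_samples = as.integer(n_samples)),
            class = "population_spec")
}

#' Build a simulation configuration
#'
#' @param populations list of [population_spec()] objects.
#' @param n_markers number of autosomal markers to simulate.
#' @param ancestral_freq_range interval within (0, 1) from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param ld_block_size markers per correlated block (1 = linkage
#'   equilibrium). Within a block, haplotypes copy a shared latent uniform
#'   with a small switching probability, so adjacent-marker genotype r^2
#'   exceeds 0.2 in expectation.
#' @param missing_rate per-call missingness probability in \[0, 1).
#' @param n_duplicates number of duplicate samples to plant.
#' @param admixture optional list of `list(pop_a, pop_b, fraction,
#'   n_samples)` entries; each admixed sample draws every haplotype block
#'   from `pop_a` with probability `fraction`, else from `pop_b`.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(populations, n_markers,
                       ancestral_freq_range = c(0.05, 0.95),
                       ld_block_size = 1L, missing_rate = 0,
                       n_duplicates = 0L, admixture = NULL, seed = 1L) {
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, TRUE, "population_spec")))
  if (n_markers < 1) stop("n_markers must be >= 1")
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop("missing_rate must be in [0, 1)")
  }
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  for (ad in admixture %||% list()) {
    if (!(ad$fraction >= 0 && ad$fraction <= 1)) {
      stop("admixture fraction must be in [0, 1]")
    }
  }
  structure(list(populations = populations, n_markers = as.integer(n_markers),
                 ancestral_freq_range = ancestral_freq_range,
                 ld_block_size = as.integer(ld_block_size),
                 missing_rate = missing_rate,
                 n_duplicates = as.integer(n_duplicates),
                 admixture = admixture, seed = as.integer(seed)),
            class = "sim_config")
}

# Marker map for simulated autosomal markers: markers are spread across
# chromosomes 1..22 in genomic order at 50-kb spacing, and LD blocks never
# span a chromosome boundary.
sim_marker_map <- function(n_markers, spacing = 50000L) {
  chrom <- as.character(rep(1:22, length.out = n_markers))
  chrom <- chrom[order(as.integer(chrom))]
  pos <- integer(n_markers)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    pos[idx] <- 1L + spacing * (seq_along(idx) - 1L)
  }
  marker_info(id = sprintf("snp%05d", seq_len(n_markers)),
              chrom = chrom, pos = pos,
              counted = rep("A", n_markers), other = rep("G", n_markers))
}

# Block index per marker: runs of ld_block_size consecutive markers, reset
# at chromosome boundaries.
sim_block_index <- function(markers, ld_block_size) {
  blk <- integer(nrow(markers))
  nxt <- 1L
  for (c in unique(markers$chrom)) {
    idx <- which(markers$chrom == c)
    within <- (seq_along(idx) - 1L) %/% ld_block_size
    blk[idx] <- nxt + within
    nxt <- nxt + max(within) + 1L
  }
  blk
}

# Draw n diploid genotype rows from per-marker haplotype frequencies `p`
# (one row of the pop_freqs matrix), with block-haplotype LD: each
# haplotype carries one latent uniform per block, refreshed per marker with
# probability `switch_prob`; the allele at marker m is (U < p[m]).
# With ld_block_size = 1 this is exactly Binomial(2, p[m]).
draw_genotypes <- function(n, p, blocks, switch_prob = 0.1) {
  n_mk <- length(p)
  out <- matrix(0L, nrow = n, ncol = n_mk)
  for (hap in 1:2) {
    u <- matrix(stats::runif(n * n_mk), nrow = n)
    refresh <- matrix(stats::runif(n * n_mk) < switch_prob, nrow = n)
    new_block <- c(TRUE, blocks[-1] != blocks[-n_mk])
    refresh[, new_block] <- TRUE
    for (m in seq_len(n_mk)) {
      if (m > 1L) {
        keep <- !refresh[, m]
        u[keep, m] <- u[keep, m - 1L]
      }
    }
    out <- out + (u < matrix(p, n, n_mk, byrow = TRUE))
  }
  storage.mode(out) <- "integer"
  out
}

# Haplotype-block source switching for admixed samples: each haplotype of
# each sample draws a source population per block.
draw_admixed <- function(n, p_a, p_b, fraction, blocks, switch_prob = 0.1) {
  n_mk <- length(p_a)
  n_blocks <- max(blocks)
  out <- matrix(0L, nrow = n, ncol = n_mk)
  for (hap in 1:2) {
    src_block <- matrix(stats::runif(n * n_blocks) < fraction, nrow = n)
    src <- src_block[, blocks, drop = FALSE]
    p_mat <- matrix(p_b, n, n_mk, byrow = TRUE)
    p_mat[src] <- matrix(p_a, n, n_mk, byrow = TRUE)[src]
    u <- matrix(stats::runif(n * n_mk), nrow = n)
    refresh <- matrix(stats::runif(n * n_mk) < switch_prob, nrow = n)
    new_block <- c(TRUE, blocks[-1] != blocks[-n_mk])
    refresh[, new_block] <- TRUE
    for (m in seq_len(n_mk)) {
      if (m > 1L) {
        keep <- !refresh[, m]
        u[keep, m] <- u[keep, m - 1L]
      }
    }
    out <- out + (u < p_mat)
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate a labelled reference panel
#'
#' Balding-Nichols model: per marker an ancestral frequency
#' `p ~ Uniform(ancestral_freq_range)`; each population's frequency
#' `p_i ~ Beta(p (1 - F_i) / F_i, (1 - p)(1 - F_i) / F_i)`; genotypes
#' `~ Binomial(2, p_i)`, with optional within-block LD (see [sim_config()]).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `panel` (a [reference_panel()]; its
#'   `pop_freqs` attribute carries the true population frequencies and LD
#'   block structure so [simulate_query()] can draw from the same model)
#'   and `truth` (data.frame: sample, population, superpopulation,
#'   admixture fraction).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    mk <- sim_marker_map(cfg$n_markers)
    blocks <- sim_block_index(mk, cfg$ld_block_size)
    p_anc <- stats::runif(cfg$n_markers, cfg$ancestral_freq_range[1],
                          cfg$ancestral_freq_range[2])
    pops <- cfg$populations
    pop_freqs <- matrix(NA_real_, nrow = length(pops), ncol = cfg$n_markers,
                        dimnames = list(vapply(pops, `[[`, "", "name"), mk$id))
    for (k in seq_along(pops)) {
      f <- pops[[k]]$fst
      pop_freqs[k, ] <- stats::rbeta(cfg$n_markers,
                                     p_anc * (1 - f) / f,
                                     (1 - p_anc) * (1 - f) / f)
    }
    # Guard against frequencies numerically at 0/1 (degenerate Beta draws).
    pop_freqs <- pmin(pmax(pop_freqs, 1e-6), 1 - 1e-6)

    rows <- list(); ids <- character(); pop_lab <- character()
    sup_lab <- character(); adm_frac <- numeric()
    sup_of <- vapply(pops, `[[`, "", "superpopulation")
    names(sup_of) <- vapply(pops, `[[`, "", "name")
    for (k in seq_along(pops)) {
      ps <- pops[[k]]
      rows[[length(rows) + 1L]] <-
        draw_genotypes(ps$n_samples, pop_freqs[k, ], blocks)
      ids <- c(ids, sprintf("%s_%03d", ps$name, seq_len(ps$n_samples)))
      pop_lab <- c(pop_lab, rep(ps$name, ps$n_samples))
      sup_lab <- c(sup_lab, rep(ps$superpopulation, ps$n_samples))
      adm_frac <- c(adm_frac, rep(1, ps$n_samples))
    }
    for (ad in cfg$admixture %||% list()) {
      ka <- match(ad$pop_a, rownames(pop_freqs))
      kb <- match(ad$pop_b, rownames(pop_freqs))
      if (is.na(ka) || is.na(kb)) stop("admixture names unknown population")
      rows[[length(rows) + 1L]] <-
        draw_admixed(ad$n_samples, pop_freqs[ka, ], pop_freqs[kb, ],
                     ad$fraction, blocks)
      lab <- paste0(ad$pop_a, "x", ad$pop_b)
      ids <- c(ids, sprintf("%s_%03d", lab, seq_len(ad$n_samples)))
      pop_lab <- c(pop_lab, rep(lab, ad$n_samples))
      major <- if (ad$fraction >= 0.5) ad$pop_a else ad$pop_b
      sup_lab <- c(sup_lab, rep(sup_of[[major]], ad$n_samples))
      adm_frac <- c(adm_frac, rep(ad$fraction, ad$n_samples))
    }
    g <- genotype_matrix(do.call(rbind, rows), mk, ids)
    panel <- reference_panel(g, pop_lab, sup_lab)
    attr(panel, "pop_freqs") <- pop_freqs
    attr(panel, "blocks") <- blocks
    attr(panel, "sup_of") <- sup_of
    truth <- data.frame(sample = ids, population = pop_lab,
                        superpopulation = sup_lab,
                        admixture_fraction = adm_frac,
                        stringsAsFactors = FALSE)
    list(panel = panel, truth = truth)
  })
}

#' Default mapping from true superpopulation to a self-report category
#'
#' Used by [simulate_query()] to assign each simulated individual the
#' ethnicity/race a truth-faithful respondent would pick. East and South
#' Asian ancestries both map to the single "Asian" race category, mirroring
#' questionnaires that offer no separate South Asian option.
#'
#' @return data.frame with columns `superpopulation`, `ethnicity`, `race`.
#' @export
default_truth_report_map <- function() {
  data.frame(
    superpopulation = c("AFR", "EUR", "ASN", "SAN", "AMR"),
    ethnicity = c("Non-Hispanic", "Non-Hispanic", "Non-Hispanic",
                  "Non-Hispanic", "Hispanic"),
    race = c("African American", "White", "Asian", "Asian", "Other"),
    stringsAsFactors = FALSE)
}

#' Simulate a query cohort from a simulated panel
#'
#' Draws query individuals from the same population allele frequencies (and
#' LD structure) as the panel, and assigns each a self-report row via a
#' truth-to-category map. Entries may override the mapped category (e.g. to
#' plant Multiracial or Other respondents for whom no superpopulation
#' prediction is expected).
#'
#' @param panel the `panel` element returned by [simulate_panel()].
#' @param spec list of entries. A pure-population entry is
#'   `list(population = "NAME", n = 10)`; an admixed entry is
#'   `list(pop_a = , pop_b = , fraction = , n = )`. Any entry may carry
#'   `ethnicity` and `race` overrides.
#' @param report_map data.frame mapping superpopulation to (ethnicity,
#'   race); default [default_truth_report_map()].
#' @param seed integer seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `report` (a
#'   [self_report()]), and `truth` (data.frame).
#' @export
simulate_query <- function(panel, spec,
                           report_map = default_truth_report_map(),
                           seed = 1L) {
  pop_freqs <- attr(panel, "pop_freqs")
  blocks <- attr(panel, "blocks")
  sup_of <- attr(panel, "sup_of")
  if (is.null(pop_freqs)) stop("panel lacks simulation attributes; use simulate_panel() output")
  with_seed(seed, {
    rows <- list(); ids <- character(); pop_lab <- character()
    sup_lab <- character(); eth <- character(); race <- character()
    adm_frac <- numeric()
    i <- 0L
    for (entry in spec) {
      n <- entry$n
      if (n == 0L) next
      i <- i + 1L
      if (!is.null(entry$population)) {
        k <- match(entry$population, rownames(pop_freqs))
        if (is.na(k)) stop("unknown population: ", entry$population)
        rows[[length(rows) + 1L]] <- draw_genotypes(n, pop_freqs[k, ], blocks)
        lab <- entry$population
        sup <- sup_of[[lab]]
        frac <- 1
      } else {
        ka <- match(entry$pop_a, rownames(pop_freqs))
        kb <- match(entry$pop_b, rownames(pop_freqs))
        if (is.na(ka) || is.na(kb)) stop("unknown population in admixed entry")
        rows[[length(rows) + 1L]] <-
          draw_admixed(n, pop_freqs[ka, ], pop_freqs[kb, ],
                       entry$fraction, blocks)
        lab <- paste0(entry$pop_a, "x", entry$pop_b)
        major <- if (entry$fraction >= 0.5) entry$pop_a else entry$pop_b
        sup <- sup_of[[major]]
        frac <- entry$fraction
      }
      m <- match(sup, report_map$superpopulation)
      e <- entry$ethnicity %||%
        (if (!is.na(m)) report_map$ethnicity[m] else "Unknown")
      r <- entry$race %||%
        (if (!is.na(m)) report_map$race[m] else "Multiracial")
      ids <- c(ids, sprintf("Q%02d_%s_%03d", i, lab, seq_len(n)))
      pop_lab <- c(pop_lab, rep(lab, n))
      sup_lab <- c(sup_lab, rep(sup, n))
      eth <- c(eth, rep(e, n)); race <- c(race, rep(r, n))
      adm_frac <- c(adm_frac, rep(frac, n))
    }
    if (length(rows) == 0L) {
      mk <- panel$genotypes$markers
      g <- genotype_matrix(matrix(integer(), 0, nrow(mk)), mk, character())
      return(list(genotypes = g,
                  report = self_report(character(), character(), character()),
                  truth = data.frame(sample = character(),
                                     population = character(),
                                     superpopulation = character(),
                                     admixture_fraction = numeric(),
                                     stringsAsFactors = FALSE)))
    }
    g <- genotype_matrix(do.call(rbind, rows), panel$genotypes$markers, ids)
    list(genotypes = g,
         report = self_report(ids, eth, race),
         truth = data.frame(sample = ids, population = pop_lab,
                            superpopulation = sup_lab,
                            admixture_fraction = adm_frac,
                            stringsAsFactors = FALSE))
  })
}

#' Mask calls at random and plant duplicate samples
#'
#' Applies per-call Bernoulli(`missing_rate`) masking, then appends
#' `n_duplicates` near-exact copies of the first `n_duplicates` samples
#' (IDs suffixed `_dup`); each copy has a small fraction of calls
#' re-randomized, as two array runs of one DNA sample would. Deterministic
#' given `seed`.
#'
#' @param g a [genotype_matrix()].
#' @param missing_rate per-call missingness probability in \[0, 1).
#' @param n_duplicates number of duplicates to plant (<= number of samples).
#' @param dup_flip_rate per-call probability that a duplicate's call is
#'   re-drawn uniformly from {0,1,2}; at most 0.01.
#' @param seed integer seed.
#' @return A `genotype_matrix`; its `duplicate_pairs` attribute lists the
#'   planted (original, duplicate) ID pairs.
#' @export
inject_missing_and_duplicates <- function(g, missing_rate = 0,
                                          n_duplicates = 0L,
                                          dup_flip_rate = 0.005,
                                          seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            dup_flip_rate >= 0, dup_flip_rate <= 0.01,
            n_duplicates <= n_samples(g))
  with_seed(seed, {
    calls <- g$calls
    samples <- g$samples
    pairs <- NULL
    if (n_duplicates > 0L) {
      src <- seq_len(n_duplicates)
      dup <- calls[src, , drop = FALSE]
      flip <- matrix(stats::runif(length(dup)) < dup_flip_rate,
                     nrow = nrow(dup))
      dup[flip] <- sample(0:2, sum(flip), replace = TRUE)
      calls <- rbind(calls, dup)
      dup_ids <- paste0(samples[src], "_dup")
      pairs <- data.frame(original = samples[src], duplicate = dup_ids,
                          stringsAsFactors = FALSE)
      samples <- c(samples, dup_ids)
    }
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(calls)) < missing_rate,
                     nrow = nrow(calls))
      calls[mask] <- NA_integer_
    }
    out <- genotype_matrix(calls, g$markers, samples)
    attr(out, "duplicate_pairs") <- pairs
    out
  })
}

#' Simulate X-chromosome genotypes consistent with sample sex
#'
#' Males are hemizygous: one allele drawn per marker, coded as homozygous
#' dosage 0 or 2 (array convention). Females are diploid under
#' Hardy-Weinberg equilibrium. Allele frequencies are uniform over
#' `freq_range`.
#'
#' @param sexes character vector `"male"`/`"female"`, one per sample; names
#'   (if set) become sample IDs.
#' @param n_markers number of X markers (0 allowed; empty matrix).
#' @param freq_range interval for counted-allele frequencies.
#' @param seed integer seed.
#' @return A `genotype_matrix` with all markers on chromosome `"X"`.
#' @export
simulate_x_chromosome <- function(sexes, n_markers,
                                  freq_range = c(0.1, 0.9), seed = 1L) {
  stopifnot(all(sexes %in% c("male", "female")))
  ids <- names(sexes) %||% sprintf("S%03d", seq_along(sexes))
  if (n_markers == 0L) {
    mk <- marker_info(character(), character(), integer(),
                      character(), character())
    return(genotype_matrix(matrix(integer(), length(sexes), 0), mk, ids))
  }
  with_seed(seed, {
    p <- stats::runif(n_markers, freq_range[1], freq_range[2])
    n <- length(sexes)
    calls <- matrix(0L, n, n_markers)
    male <- sexes == "male"
    if (any(male)) {
      calls[male, ] <- 2L * (matrix(stats::runif(sum(male) * n_markers),
                                    ncol = n_markers) <
                             matrix(p, sum(male), n_markers, byrow = TRUE))
    }
    if (any(!male)) {
      u1 <- matrix(stats::runif(sum(!male) * n_markers), ncol = n_markers)
      u2 <- matrix(stats::runif(sum(!male) * n_markers), ncol = n_markers)
      pm <- matrix(p, sum(!male), n_markers, byrow = TRUE)
      calls[!male, ] <- (u1 < pm) + (u2 < pm)
    }
    storage.mode(calls) <- "integer"
    mk <- marker_info(id = sprintf("xsnp%05d", seq_len(n_markers)),
                      chrom = rep("X", n_markers),
                      pos = 1L + 50000L * (seq_len(n_markers) - 1L),
                      counted = rep("A", n_markers),
                      other = rep("G", n_markers))
    genotype_matrix(calls, mk, ids)
  })
}
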