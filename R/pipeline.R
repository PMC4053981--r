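# End-to-end orchestration: (simulate | load) -> QC -> AIM selection ->
# joint MDS -> LDA -> concordance, with stage outputs written to disk and
# a manifest recording parameters, seed and file digests. Each stage
# consumes only objects produced by earlier stages, so any stage can be
# re-run from its predecessors' files.

#' Build a pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()], plus `query_spec`) or `inputs`
#' (paths to real reference/query data) must be given.
#'
#' @param sim a [sim_config()] for the reference panel, or `NULL`.
#' @param query_spec query cohort specification for [simulate_query()]
#'   (simulation mode only).
#' @param inputs list with elements `reference` (VCF path or PLINK text
#'   prefix), `labels` (TSV: sample, population, superpopulation), `query`
#'   (VCF path or PLINK text prefix), `self_report` (TSV), or `NULL`.
#' @param call_rate_min,maf_min,pi_hat_max QC thresholds; defaults 0.90,
#'   0.10, 0.95.
#' @param r2_max,window_bp AIM selection LD parameters; defaults 0.2, 1 Mb.
#' @param max_markers optional cap on selected AIMs.
#' @param n_mds_components MDS dimensions for the classifier; default 20.
#' @param level classification level, `"superpopulation"` (default) or
#'   `"population"`.
#' @param n_x_markers simulation mode: X markers to generate for the sex
#'   check (0 skips it).
#' @param out_dir output directory.
#' @param seed integer seed driving every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, query_spec = NULL, inputs = NULL,
                            call_rate_min = 0.90, maf_min = 0.10,
                            pi_hat_max = 0.95, r2_max = 0.2,
                            window_bp = 1000000L, max_markers = NULL,
                            n_mds_components = 20L,
                            level = c("superpopulation", "population"),
                            n_x_markers = 0L, out_dir = tempfile("run_"),
                            seed = 1L) {
  level <- match.arg(level)
  if (is.null(sim) == is.null(inputs)) {
    stop("provide exactly one of `sim` or `inputs`")
  }
  if (!is.null(sim) && is.null(query_spec)) {
    stop("simulation mode needs `query_spec`")
  }
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            maf_min >= 0, maf_min < 0.5,
            pi_hat_max > 0, pi_hat_max <= 1,
            r2_max > 0, r2_max <= 1, window_bp >= 0,
            n_mds_components >= 1)
  structure(list(sim = sim, query_spec = query_spec, inputs = inputs,
                 call_rate_min = call_rate_min, maf_min = maf_min,
                 pi_hat_max = pi_hat_max, r2_max = r2_max,
                 window_bp = as.integer(window_bp),
                 max_markers = max_markers,
                 n_mds_components = as.integer(n_mds_components),
                 level = level, n_x_markers = as.integer(n_x_markers),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_genotype_input <- function(path) {
  if (file.exists(paste0(path, ".ped"))) read_plink_text(path)
  else read_vcf(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full ancestry-concordance pipeline
#'
#' Stages: acquire reference and query genotypes (simulated or loaded),
#' sample QC on the query cohort (call rate, optional X-based sex check,
#' duplicate removal), AIM selection on the reference panel, joint
#' IBS-distance MDS of reference plus kept query samples, LDA
#' classification of the queries, and concordance against self-report.
#' All tables are written under `cfg$out_dir`; a `manifest.json` records
#' package version, seed, parameters and MD5 digests of every output, and
#' is byte-identical across re-runs with the same configuration.
#'
#' @param cfg a [pipeline_config()].
#' @return list: `qc`, `scores`, `mds`, `assignments`, `crosstab`,
#'   `stats`, `truth` (simulation mode), `manifest`, invisibly also
#'   written under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  truth <- NULL
  if (!is.null(cfg$sim)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- as.integer(derive_seed(cfg$seed, 1))
    pan <- stage("simulate_panel", simulate_panel(sim_cfg))
    panel <- pan$panel
    qry <- stage("simulate_query",
                 simulate_query(panel, cfg$query_spec,
                                seed = derive_seed(cfg$seed, 2)))
    query <- stage("inject_missing_and_duplicates",
                   inject_missing_and_duplicates(
                     qry$genotypes, missing_rate = sim_cfg$missing_rate,
                     n_duplicates = sim_cfg$n_duplicates,
                     seed = derive_seed(cfg$seed, 3)))
    reports <- qry$report
    dup_pairs <- attr(query, "duplicate_pairs")
    if (!is.null(dup_pairs)) {
      extra <- reports[match(dup_pairs$original, reports$sample), ]
      extra$sample <- dup_pairs$duplicate
      reports <- rbind(reports, extra)
      class(reports) <- c("self_report", "data.frame")
    }
    truth <- list(panel = pan$truth, query = qry$truth)
    x_geno <- NULL
    sexes <- NULL
    if (cfg$n_x_markers > 0) {
      sexes <- stats::setNames(
        rep(c("female", "male"), length.out = n_samples(query)),
        query$samples)
      x_geno <- simulate_x_chromosome(sexes, cfg$n_x_markers,
                                      seed = derive_seed(cfg$seed, 4))
    }
    log_msg("simulated panel: %d reference, %d query samples, %d markers",
            n_samples(panel$genotypes), n_samples(query), n_markers(query))
  } else {
    inp <- cfg$inputs
    ref_g <- stage("read_reference", read_genotype_input(inp$reference))
    labels <- stage("read_labels", read_labels_tsv(inp$labels))
    m <- match(ref_g$samples, labels$sample)
    if (anyNA(m)) stop("reference sample(s) missing from labels TSV")
    panel <- reference_panel(ref_g, labels$population[m],
                             labels$superpopulation[m])
    query <- stage("read_query", read_genotype_input(inp$query))
    reports <- stage("read_self_report", read_self_report_tsv(inp$self_report))
    harmon <- stage("intersect_markers",
                    intersect_markers(panel$genotypes, query))
    panel <- reference_panel(harmon$a, panel$population, panel$superpopulation)
    query <- harmon$b
    x_geno <- NULL; sexes <- NULL
    log_msg("loaded %d reference and %d query samples over %d shared markers",
            n_samples(panel$genotypes), n_samples(query), n_markers(query))
  }

  qc <- stage("qc", qc_report(query, x_genotypes = x_geno,
                              reported_sex = sexes,
                              call_rate_min = cfg$call_rate_min,
                              maf_min = cfg$maf_min,
                              pi_hat_max = cfg$pi_hat_max))
  log_msg("QC applied (call rate >= %.2f, PI_HAT < %.2f): kept %d of %d query samples",
          cfg$call_rate_min, cfg$pi_hat_max, length(qc$keep), n_samples(query))
  write_tsv(qc$samples, file.path(cfg$out_dir, "qc_samples.tsv"))
  query <- subset_genotypes(query, samples = qc$keep)
  reports <- reports[reports$sample %in% qc$keep, , drop = FALSE]

  scores <- stage("select_aims",
                  select_aims(panel, group_field = cfg$level,
                              r2_max = cfg$r2_max,
                              window_bp = cfg$window_bp,
                              max_markers = cfg$max_markers))
  aims <- scores$id[scores$selected]
  log_msg("selected %d AIMs (r^2 < %.2f within %d bp)", length(aims),
          cfg$r2_max, cfg$window_bp)
  write_tsv(scores, file.path(cfg$out_dir, "marker_scores.tsv"))

  proj <- stage("mds", project_joint(panel$genotypes, query,
                                     marker_ids = aims,
                                     n_components = cfg$n_mds_components))
  coords <- proj$mds$coordinates
  write_tsv(data.frame(sample = proj$mds$samples, coords,
                       stringsAsFactors = FALSE),
            file.path(cfg$out_dir, "mds_coordinates.tsv"))

  ref_labels <- panel[[cfg$level]][match(
    proj$mds$samples[proj$is_reference], panel$genotypes$samples)]
  model <- stage("fit_lda",
                 fit_lda(coords[proj$is_reference, , drop = FALSE], ref_labels))
  assignments <- stage("predict",
                       predict(model, coords[!proj$is_reference, , drop = FALSE]))
  write_tsv(as.data.frame(assignments),
            file.path(cfg$out_dir, "assignments.tsv"))

  ct <- stage("crosstab", build_crosstab(reports, assignments))
  write_tsv(as.data.frame(ct), file.path(cfg$out_dir, "crosstab.tsv"))
  stats <- stage("concordance", concordance_stats(ct))
  log_msg("concordance: %d/%d (%.1f%%)", stats$n_concordant,
          stats$n_evaluable, stats$rate_pct)
  jsonlite::write_json(
    list(n_evaluable = stats$n_evaluable, n_concordant = stats$n_concordant,
         n_discordant = stats$n_discordant, fraction = stats$fraction,
         rate_pct = stats$rate_pct,
         no_prediction = list(
           n = stats$no_prediction$n,
           distribution = as.list(stats$no_prediction$distribution))),
    file.path(cfg$out_dir, "concordance_stats.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  params <- cfg[c("call_rate_min", "maf_min", "pi_hat_max", "r2_max",
                  "window_bp", "n_mds_components", "level", "n_x_markers")]
  out_files <- c("qc_samples.tsv", "marker_scores.tsv",
                 "mds_coordinates.tsv", "assignments.tsv", "crosstab.tsv",
                 "concordance_stats.json")
  digests <- tools::md5sum(file.path(cfg$out_dir, out_files))
  names(digests) <- out_files
  manifest <- list(package = "ancestrycheck",
                   version = as.character(utils::packageVersion("ancestrycheck")),
                   seed = cfg$seed, parameters = params,
                   n_selected_aims = length(aims),
                   files = as.list(digests))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qc = qc, scores = scores, mds = proj$mds,
                 is_reference = proj$is_reference, model = model,
                 assignments = assignments, crosstab = ct, stats = stats,
                 truth = truth, manifest = manifest))
}
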