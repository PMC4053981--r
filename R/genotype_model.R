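# Core data types and file I/O for genotypes, marker maps, panel labels and
# self-report metadata.

#' Construct a marker map
#'
#' A marker map describes the variants of a genotype matrix: identifier,
#' chromosome, 1-based physical position, and the ordered allele pair with the
#' counted allele first (dosages elsewhere in the package count copies of this
#' allele).
#'
#' @param id character vector of unique marker identifiers.
#' @param chrom character vector; autosomes `"1"`..`"22"` or `"X"`.
#' @param pos integer vector of 1-based base-pair positions.
#' @param counted,other allele symbols; `counted` is the allele whose copies
#'   the dosage counts (the ALT allele when written as VCF).
#' @return A `data.frame` with columns `id`, `chrom`, `pos`, `counted`,
#'   `other`.
#' @export
marker_info <- function(id, chrom, pos, counted, other) {
  id <- as.character(id); chrom <- as.character(chrom)
  pos <- as.integer(pos)
  counted <- as.character(counted); other <- as.character(other)
  n <- length(id)
  stopifnot(length(chrom) == n, length(pos) == n,
            length(counted) == n, length(other) == n)
  if (anyDuplicated(id)) stop("marker ids must be unique")
  if (any(pos < 1L)) stop("marker positions must be >= 1")
  if (any(counted == other)) stop("the two alleles of a marker must differ")
  ok_chrom <- chrom %in% c(as.character(1:22), "X")
  if (!all(ok_chrom)) {
    stop("unsupported chromosome label(s): ",
         paste(unique(chrom[!ok_chrom]), collapse = ", "))
  }
  data.frame(id = id, chrom = chrom, pos = pos,
             counted = counted, other = other,
             stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' The central container: an integer matrix of diploid allele dosages
#' (samples in rows, markers in columns) together with its marker map.
#' Dosage is the number of copies of the counted allele, in `{0, 1, 2}`;
#' missing calls are `NA` (never 0).
#'
#' @param calls integer matrix, samples x markers; values in `{0, 1, 2, NA}`.
#' @param markers marker map as returned by [marker_info()]; one row per
#'   column of `calls`.
#' @param samples character vector of unique sample IDs, one per row of
#'   `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.character(samples)
  if (nrow(calls) != length(samples)) {
    stop("nrow(calls) must equal length(samples)")
  }
  if (ncol(calls) != nrow(markers)) {
    stop("ncol(calls) must equal nrow(markers)")
  }
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(calls) <- list(samples, markers$id)
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.2f%% missing)\n",
              n_samples(x), n_markers(x),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of samples / markers in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname n_samples
#' @export
n_markers <- function(g) nrow(g$markers)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param samples,markers index vectors (logical, integer, or character IDs)
#'   selecting rows/columns to keep; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_along(g$samples) else samples
  if (is.character(si)) si <- match(si, g$samples)
  mi <- if (is.null(markers)) seq_len(n_markers(g)) else markers
  if (is.character(mi)) mi <- match(mi, g$markers$id)
  if (anyNA(si)) stop("unknown sample ID in subset")
  if (anyNA(mi)) stop("unknown marker ID in subset")
  genotype_matrix(g$calls[si, mi, drop = FALSE],
                  g$markers[mi, , drop = FALSE],
                  g$samples[si])
}

#' Stack two genotype matrices over the same markers
#'
#' Row-binds samples of `a` and `b`; both must have identical marker maps
#' (use [intersect_markers()] first if they do not).
#'
#' @param a,b `genotype_matrix` objects over the same markers.
#' @return A combined `genotype_matrix`.
#' @export
bind_samples <- function(a, b) {
  if (!identical(a$markers$id, b$markers$id)) {
    stop("marker maps differ; run intersect_markers() first")
  }
  genotype_matrix(rbind(a$calls, b$calls), a$markers,
                  c(a$samples, b$samples))
}

#' Construct a labelled reference panel
#'
#' A reference panel is a genotype matrix whose samples carry population and
#' superpopulation labels (for example the 1000 Genomes populations grouped
#' into the AFR, EUR, ASN, AMR, SAN superpopulations). Every population must
#' map to exactly one superpopulation.
#'
#' @param genotypes a `genotype_matrix`.
#' @param population character vector, one population label per sample.
#' @param superpopulation character vector, one superpopulation label per
#'   sample.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(genotypes, population, superpopulation) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  population <- as.character(population)
  superpopulation <- as.character(superpopulation)
  n <- n_samples(genotypes)
  if (length(population) != n || length(superpopulation) != n) {
    stop("need one population and one superpopulation label per sample")
  }
  map <- unique(data.frame(population, superpopulation,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(map$population)) {
    stop("a population maps to more than one superpopulation")
  }
  structure(list(genotypes = genotypes, population = population,
                 superpopulation = superpopulation),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d samples, %d markers, %d populations in %d superpopulations\n",
              n_samples(x$genotypes), n_markers(x$genotypes),
              length(unique(x$population)),
              length(unique(x$superpopulation))))
  invisible(x)
}

#' Construct a self-report table
#'
#' Per-sample self-reported ethnicity, race and sex, as collected by
#' questionnaire. `Multiracial` stands for any multi-category race selection.
#'
#' @param sample sample IDs.
#' @param ethnicity one of `"Hispanic"`, `"Non-Hispanic"`, `"Unknown"`.
#' @param race one of `"African American"`, `"American Indian or Alaska
#'   Native"`, `"Asian"`, `"Native Hawaiian or Other Pacific Islander"`,
#'   `"White"`, `"Other"`, `"Multiracial"`.
#' @param reported_sex one of `"female"`, `"male"`, `"unknown"`.
#' @return A `data.frame` of class `self_report`.
#' @export
self_report <- function(sample, ethnicity, race,
                        reported_sex = rep("unknown", length(sample))) {
  sample <- as.character(sample)
  ethnicity <- as.character(ethnicity)
  race <- as.character(race)
  reported_sex <- as.character(reported_sex)
  stopifnot(length(ethnicity) == length(sample),
            length(race) == length(sample),
            length(reported_sex) == length(sample))
  if (!all(ethnicity %in% ethnicity_levels())) stop("invalid ethnicity value")
  if (!all(race %in% race_levels())) stop("invalid race value")
  if (!all(reported_sex %in% c("female", "male", "unknown"))) {
    stop("invalid reported_sex value")
  }
  out <- data.frame(sample = sample, ethnicity = ethnicity, race = race,
                    reported_sex = reported_sex, stringsAsFactors = FALSE)
  class(out) <- c("self_report", "data.frame")
  out
}

#' Category levels for self-reported ethnicity and race
#' @return character vector of allowed values.
#' @export
ethnicity_levels <- function() c("Hispanic", "Non-Hispanic", "Unknown")

#' @rdname ethnicity_levels
#' @export
race_levels <- function() {
  c("African American", "American Indian or Alaska Native", "Asian",
    "Native Hawaiian or Other Pacific Islander", "White", "Other",
    "Multiracial")
}

# ---------------------------------------------------------------------------
# VCF I/O

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a diploid VCF 4.x file into a [genotype_matrix()].
#' Dosage counts the ALT allele; `./.` becomes `NA`. Multi-allelic records
#' are rejected by default because exome-array content is biallelic.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param multiallelic `"error"` (default) to reject records with more than
#'   one ALT allele, or `"first"` to keep the first ALT and count it.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, multiallelic = c("error", "first")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error") {
      stop(sum(multi), " multi-allelic record(s); set multiallelic = \"first\" to keep the first ALT")
    }
    alt <- sub(",.*$", "", alt)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt[gt == "."] <- NA_character_
  gt_flat <- gsub("|", "/", gt, fixed = TRUE)
  known <- is.na(gt_flat) | gt_flat %in% c("0/0", "0/1", "1/0", "1/1", "./.",
                                           "./0", "0/.", "./1", "1/.")
  if (!all(known)) {
    bad <- unique(gt_flat[!known])
    stop("non-diploid or non-biallelic GT value(s): ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  dose <- matrix(NA_integer_, nrow = nrow(gt_flat), ncol = ncol(gt_flat))
  dose[gt_flat == "0/0"] <- 0L
  dose[gt_flat %in% c("0/1", "1/0")] <- 1L
  dose[gt_flat == "1/1"] <- 2L
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  mk <- marker_info(id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    counted = alt, other = fix[, "REF"])
  genotype_matrix(t(dose), mk, colnames(gt))
}

#' Write genotypes to a VCF file
#'
#' Emits plain-text VCF 4.2 with a GT-only FORMAT. The counted allele is
#' written as ALT, so [read_vcf()] round-trips calls exactly.
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  calls <- g$calls
  body <- matrix("./.", nrow = n_markers(g), ncol = n_samples(g))
  ok <- !is.na(calls)
  body[t(ok)] <- gt_code[t(calls)[t(ok)] + 1L]
  mk <- g$markers
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t"),
    paste(mk$chrom, mk$pos, mk$id, mk$other, mk$counted, ".", "PASS", ".",
          "GT", apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PLINK-style transposed text (.ped/.map, plus a .frq companion fixing the
# counted allele, in the style of PLINK --freq output)

#' Read genotypes from PLINK-style .ped/.map text
#'
#' Reads `<prefix>.ped` and `<prefix>.map` (whitespace-delimited text).
#' Allele pairs are converted to counted-allele dosage; `0 0` becomes `NA`.
#' If `<prefix>.frq` exists its A1 column fixes the counted allele per
#' marker; otherwise the minor allele observed in the file is counted
#' (alphabetical tie-break).
#'
#' @param prefix path prefix of the fileset.
#' @return A `genotype_matrix`.
#' @export
read_plink_text <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path)) stop("missing file: ", map_path)
  if (!file.exists(ped_path)) stop("missing file: ", ped_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) != 4) stop(".map must have 4 columns (chrom id cm pos)")
  names(map) <- c("chrom", "id", "cm", "pos")
  n_mk <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  toks <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_mk
  nf <- lengths(toks)
  if (any(nf != want)) {
    stop(sprintf(".ped row %d has %d fields, expected %d",
                 which(nf != want)[1], nf[nf != want][1], want))
  }
  ped <- do.call(rbind, toks)
  samples <- ped[, 2]
  a1 <- ped[, 6L + 2L * seq_len(n_mk) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_mk), drop = FALSE]
  if (any((a1 == "0") != (a2 == "0"))) {
    stop("half-missing genotype (one allele '0') in .ped")
  }

  frq_path <- paste0(prefix, ".frq")
  if (file.exists(frq_path)) {
    frq <- utils::read.table(frq_path, header = TRUE,
                             colClasses = "character")
    m <- match(map$id, frq$SNP)
    if (anyNA(m)) stop(".frq does not cover all .map markers")
    counted <- frq$A1[m]
    other <- frq$A2[m]
  } else {
    counted <- other <- character(n_mk)
    for (j in seq_len(n_mk)) {
      al <- c(a1[, j], a2[, j])
      al <- al[al != "0"]
      tab <- sort(table(al))
      if (length(tab) == 1) {
        counted[j] <- names(tab)
        other[j] <- if (names(tab) == "A") "B" else "A"
      } else if (length(tab) == 2) {
        nm <- names(tab)
        if (tab[1] == tab[2]) nm <- sort(nm)
        counted[j] <- nm[1]; other[j] <- nm[2]
      } else {
        stop("marker ", map$id[j], " has >2 alleles in .ped")
      }
    }
  }
  dose <- (a1 == matrix(counted, nrow(ped), n_mk, byrow = TRUE)) +
          (a2 == matrix(counted, nrow(ped), n_mk, byrow = TRUE))
  dose[a1 == "0"] <- NA_integer_
  storage.mode(dose) <- "integer"
  mk <- marker_info(id = map$id, chrom = map$chrom,
                    pos = as.integer(map$pos),
                    counted = counted, other = other)
  genotype_matrix(dose, mk, samples)
}

#' Write genotypes as PLINK-style .ped/.map text
#'
#' Writes `<prefix>.ped`, `<prefix>.map` and `<prefix>.frq` (the latter
#' fixes the counted allele so [read_plink_text()] round-trips exactly).
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(g, prefix) {
  mk <- g$markers
  utils::write.table(
    data.frame(mk$chrom, mk$id, 0, mk$pos),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  n_mk <- n_markers(g)
  a1 <- matrix(rep(mk$counted, each = n_samples(g)), ncol = n_mk)
  a2 <- a1
  oth <- matrix(rep(mk$other, each = n_samples(g)), ncol = n_mk)
  is0 <- which(!is.na(g$calls) & g$calls == 0L)
  le1 <- which(!is.na(g$calls) & g$calls <= 1L)
  a1[is0] <- oth[is0]
  a2[le1] <- oth[le1]
  miss <- which(is.na(g$calls))
  a1[miss] <- "0"
  a2[miss] <- "0"
  inter <- matrix("", nrow = n_samples(g), ncol = 2L * n_mk)
  inter[, 2L * seq_len(n_mk) - 1L] <- a1
  inter[, 2L * seq_len(n_mk)] <- a2
  ped <- cbind(g$samples, g$samples, "0", "0", "0", "-9", inter)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")

  p <- group_allele_freqs(g$calls, rep("all", n_samples(g)))[1, ]
  utils::write.table(
    data.frame(CHR = mk$chrom, SNP = mk$id, A1 = mk$counted, A2 = mk$other,
               MAF = round(p, 6),
               NCHROBS = 2L * colSums(!is.na(g$calls))),
    paste0(prefix, ".frq"),
    quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(prefix)
}

# ---------------------------------------------------------------------------
# Metadata TSVs

#' Read/write panel labels and self-report tables as headered TSV
#'
#' Labels TSV columns: `sample`, `population`, `superpopulation`.
#' Self-report TSV columns: `sample`, `ethnicity`, `race`, `reported_sex`.
#'
#' @param path TSV file path.
#' @param x table to write.
#' @return `read_labels_tsv` a data.frame; `read_self_report_tsv` a
#'   [self_report()] table.
#' @export
read_labels_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character")
}

#' @rdname read_labels_tsv
#' @export
read_self_report_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  self_report(d$sample, d$ethnicity, d$race, d$reported_sex)
}

#' @rdname read_labels_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Restrict two genotype matrices to their shared markers
#'
#' Both matrices are restricted to the marker IDs they share, in the marker
#' order of `a`. Allele orientation is reconciled by symbol: where `b`'s
#' counted/other pair is swapped relative to `a`, `b`'s dosages are flipped
#' to `2 - d`. Shared IDs whose allele pairs cannot be reconciled are
#' dropped with a warning. No strand flipping is attempted.
#'
#' @param a,b `genotype_matrix` objects.
#' @return A list with elements `a` and `b`, both over the shared markers.
#' @export
intersect_markers <- function(a, b) {
  shared <- intersect(a$markers$id, b$markers$id)
  if (length(shared) == 0) stop("no shared marker IDs")
  ia <- match(shared, a$markers$id)
  ib <- match(shared, b$markers$id)
  ma <- a$markers[ia, ]
  mb <- b$markers[ib, ]
  same <- ma$counted == mb$counted & ma$other == mb$other
  flip <- ma$counted == mb$other & ma$other == mb$counted
  keep <- same | flip
  if (!all(keep)) {
    warning(sum(!keep), " shared marker(s) dropped: irreconcilable alleles")
  }
  if (!any(keep)) stop("no shared marker IDs with reconcilable alleles")
  a2 <- subset_genotypes(a, markers = ia[keep])
  b2 <- subset_genotypes(b, markers = ib[keep])
  flip_k <- flip[keep]
  if (any(flip_k)) {
    b2$calls[, flip_k] <- 2L - b2$calls[, flip_k]
    b2$markers$counted[flip_k] <- a2$markers$counted[flip_k]
    b2$markers$other[flip_k] <- a2$markers$other[flip_k]
  }
  list(a = a2, b = b2)
}

# Per-group counted-allele frequencies with pairwise-complete missingness
# handling (no pseudocounts). Returns groups x markers matrix; a group with
# no calls at a marker gets NA.
group_allele_freqs <- function(calls, groups) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  out <- matrix(NA_real_, nrow = length(gl), ncol = ncol(calls),
                dimnames = list(gl, colnames(calls)))
  for (k in seq_along(gl)) {
    rows <- groups == gl[k]
    cc <- calls[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(cc))
    s <- colSums(cc, na.rm = TRUE)
    out[k, ] <- ifelse(n_obs > 0, s / (2 * n_obs), NA_real_)
  }
  out
}
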