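pair_metadata <- function(sheet) {
  sheet |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(
      a = .data$sample_id[1], b = .data$sample_id[2],
      zygosity = .data$zygosity[1],
      same_chip = .data$beadchip[1] == .data$beadchip[2],
      opposite_sex = .data$sex[1] != .data$sex[2],
      .groups = "drop"
    )
}

d_wide <- function(diffs, param) {
  diffs |>
    dplyr::select("a", "b", "chrom", dplyr::all_of(param)) |>
    tidyr::pivot_wider(names_from = "chrom", values_from = dplyr::all_of(param)) |>
    dplyr::select(-"a", -"b")
}

compare_d_sets <- function(g_diffs, l_diffs, param, label) {
  chroms <- sort(intersect(unique(g_diffs$chrom), unique(l_diffs$chrom)))
  p <- vapply(chroms, function(ch) {
    mann_whitney_one_sided(g_diffs[[param]][g_diffs$chrom == ch],
                           l_diffs[[param]][l_diffs$chrom == ch])$p
  }, numeric(1))
  est <- dplyr::bind_rows(d_wide(g_diffs, param), d_wide(l_diffs, param))
  cmb <- combine_correlated_pvalues(p, estimates = est)
  tibble::tibble(
    comparison = label, param = sub("^d_", "", param),
    n_greater = length(unique(paste(g_diffs$a, g_diffs$b))),
    n_lesser = length(unique(paste(l_diffs$a, l_diffs$b))),
    p_chrom = list(stats::setNames(p, chroms)),
    p_combined = cmb$p_combined
  )
}

#' Pairing-based batch and genetics contrasts
#'
#' Runs the eight squared-difference comparisons that separate technical
#' (plate, BeadChip) from genetic (zygosity) and sex structure in the
#' dependency parameters: random vs plate-matched pairing, plate- vs
#' plate-and-chip-matched pairing, both matched schemes vs true twins,
#' same- vs different-chip twins by zygosity, DZ vs MZ, and opposite- vs
#' same-sex DZ pairs. For the random schemes the representative repeat
#' (middle rank by median D over `n_repeats` repeats) is used. Each
#' comparison is a per-chromosome one-sided Mann-Whitney test combined
#' across chromosomes by the correlated extension of Fisher's method.
#'
#' @param fits Parameter table from [fit_cohort()].
#' @param sheet Sample sheet tibble.
#' @param seed Pairing seed.
#' @param n_repeats Random-pairing repeats (default 100).
#' @return A tibble with one row per comparison x parameter
#'   (`comparison`, `param`, group sizes, `p_chrom` list-column,
#'   `p_combined`); the representative pairings are attached as the
#'   `"pairings"` attribute, and pooled median D per scheme as the
#'   `"scheme_median_d"` attribute.
#' @export
pairing_tests <- function(fits, sheet, seed = 1L, n_repeats = 100) {
  sheet <- sheet[sheet$sample_id %in% fits$sample_id, ]
  meta <- pair_metadata(sheet)
  true_pairs <- build_pairing(sheet, "true_twins")
  d_true <- pair_squared_diffs(fits, true_pairs)
  d_true_meta <- dplyr::left_join(
    d_true,
    dplyr::select(meta, "a", "zygosity", "same_chip", "opposite_sex"),
    by = "a"
  )
  schemes <- c("random", "matched_plate", "matched_plate_chip")
  all_d <- lapply(stats::setNames(schemes, schemes), function(s) {
    pr <- build_pairing(sheet, s, seed = derive_seed(seed, match(s, schemes)),
                        n_repeats = n_repeats)
    pair_squared_diffs(fits, pr)
  })

  rows <- list(); reps <- list()
  med_rows <- list()
  for (param in c("d_logtau", "d_logkappa")) {
    rep_d <- lapply(all_d, representative_pairing, param = param)
    reps[[param]] <- rep_d
    rows <- c(rows, list(
      compare_d_sets(rep_d$random, rep_d$matched_plate, param,
                     "random > matched_plate"),
      compare_d_sets(rep_d$matched_plate, rep_d$matched_plate_chip, param,
                     "matched_plate > matched_plate_chip"),
      compare_d_sets(rep_d$matched_plate, d_true, param,
                     "matched_plate > true_twins"),
      compare_d_sets(rep_d$matched_plate_chip, d_true, param,
                     "matched_plate_chip > true_twins")
    ))
    mz <- d_true_meta[d_true_meta$zygosity == "MZ", ]
    dz <- d_true_meta[d_true_meta$zygosity == "DZ", ]
    if (any(!mz$same_chip) && any(mz$same_chip)) {
      rows <- c(rows, list(compare_d_sets(
        mz[!mz$same_chip, ], mz[mz$same_chip, ], param,
        "MZ different chip > MZ same chip")))
    }
    if (any(!dz$same_chip) && any(dz$same_chip)) {
      rows <- c(rows, list(compare_d_sets(
        dz[!dz$same_chip, ], dz[dz$same_chip, ], param,
        "DZ different chip > DZ same chip")))
    }
    rows <- c(rows, list(compare_d_sets(dz, mz, param, "DZ > MZ")))
    if (any(dz$opposite_sex) && any(!dz$opposite_sex)) {
      rows <- c(rows, list(compare_d_sets(
        dz[dz$opposite_sex, ], dz[!dz$opposite_sex, ], param,
        "opposite-sex DZ > same-sex DZ")))
    }
    meds <- c(true_twins = stats::median(d_true[[param]]),
              vapply(rep_d, function(d) stats::median(d[[param]]), numeric(1)))
    med_rows[[param]] <- tibble::tibble(
      scheme = names(meds), param = sub("^d_", "", param),
      median_d = unname(meds)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pairings") <- reps
  attr(out, "scheme_median_d") <- dplyr::bind_rows(med_rows)
  attr(out, "seed") <- seed
  out
}

#' Full cohort-level statistical report
#'
#' Assembles all cohort analyses of a fitted parameter table: ICC of
#' log(tau) and log(kappa) across chromosome replicates (one individual
#' per family), the eight pairing contrasts, per-scheme median D, the
#' relative-range chromosome profile with Spearman correlations against
#' relative gene density and relative island proportion (when supplied),
#' and the age-group contrasts (young-greater direction for log tau and
#' log kappa, old-greater for variance explained).
#'
#' @param fits Parameter table from [fit_cohort()].
#' @param sheet Sample sheet tibble.
#' @param manifest Optional probe manifest (enables the island-proportion
#'   correlation).
#' @param gene_density Optional tibble with `chrom`, `genes_per_mb`.
#' @param seed Seed for the ICC family selection and pairings.
#' @param n_repeats Random-pairing repeats (default 100).
#' @param young_max,old_min Age-group cut points.
#' @return A list of class `cohort_report`.
#' @export
cohort_report <- function(fits, sheet, manifest = NULL, gene_density = NULL,
                          seed = 1L, n_repeats = 100,
                          young_max = 40, old_min = 50) {
  tab <- dplyr::left_join(fits, sheet, by = "sample_id")
  sel <- one_per_family(sheet[sheet$sample_id %in% fits$sample_id, ],
                        seed = derive_seed(seed, 11))
  icc_tab <- fits[fits$sample_id %in% sel, ]
  icc <- list(
    logtau = icc_oneway(icc_tab, .data$post_mean_logtau, .data$sample_id),
    logkappa = icc_oneway(icc_tab, .data$post_mean_logkappa, .data$sample_id)
  )
  ptests <- pairing_tests(fits, sheet, seed = derive_seed(seed, 12),
                          n_repeats = n_repeats)
  rel_r <- relative_range(fits)
  correlations <- list()
  if (nrow(rel_r) < 4) {
    message("fewer than 4 chromosomes; skipping relative-range correlations")
  } else {
    if (!is.null(gene_density)) {
      gd <- gene_density[match(rel_r$chrom, gene_density$chrom), ]
      correlations$gene_density <- spearman_with_ci(
        rel_r$rel_range_median, gd$genes_per_mb / stats::median(gd$genes_per_mb))
    }
    if (!is.null(manifest)) {
      ip <- island_proportions(manifest)
      ip <- ip[match(rel_r$chrom, ip$chrom), ]
      correlations$island_proportion <- spearman_with_ci(
        rel_r$rel_range_median, ip$rel_prop)
    }
  }
  age_params <- tryCatch(
    age_group_contrast(tab, c("post_mean_logtau", "post_mean_logkappa"),
                       young_max, old_min, direction = "young_greater"),
    error = function(e) {
      message("age contrast skipped: ", conditionMessage(e))
      NULL
    }
  )
  age_ve <- if (is.null(age_params)) NULL else {
    age_group_contrast(tab, "var_explained",
                       young_max, old_min, direction = "old_greater")
  }
  structure(
    list(
      icc = icc, icc_samples = sel,
      pairing_tests = ptests,
      scheme_median_d = attr(ptests, "scheme_median_d"),
      relative_range = rel_r, correlations = correlations,
      age_contrast = list(
        parameters = age_params, variance_explained = age_ve
      ),
      n_fits = nrow(fits), n_samples = length(unique(fits$sample_id)),
      seed = seed
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort dependency report: %d fits, %d samples\n",
              x$n_fits, x$n_samples))
  cat(sprintf("  ICC log(tau)   = %.3f [%.3f, %.3f]\n",
              x$icc$logtau$icc, x$icc$logtau$ci_low, x$icc$logtau$ci_high))
  cat(sprintf("  ICC log(kappa) = %.3f [%.3f, %.3f]\n",
              x$icc$logkappa$icc, x$icc$logkappa$ci_low, x$icc$logkappa$ci_high))
  cat("  Median D by pairing scheme (log tau):\n")
  md <- x$scheme_median_d
  md <- md[md$param == "logtau", ]
  for (i in seq_len(nrow(md))) {
    cat(sprintf("    %-20s %.4f\n", md$scheme[i], md$median_d[i]))
  }
  cat("  Pairing contrasts (combined p):\n")
  pt <- x$pairing_tests
  for (i in seq_len(nrow(pt))) {
    cat(sprintf("    %-40s %-8s %.3g\n", pt$comparison[i], pt$param[i],
                pt$p_combined[i]))
  }
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("  Spearman rel. range vs %s: rho = %.2f [%.2f, %.2f], p = %.2g\n",
                nm, co$rho, co$ci_low, co$ci_high, co$p))
  }
  if (!is.null(x$age_contrast$parameters)) {
    ac <- x$age_contrast$parameters$combined
    for (i in seq_len(nrow(ac))) {
      cat(sprintf("  Age contrast %s: combined p = %.3g\n", ac$param[i],
                  ac$p_combined[i]))
    }
    cat(sprintf("  Age contrast var_explained (old greater): combined p = %.3g\n",
                x$age_contrast$variance_explained$combined$p_combined))
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Writes a JSON summary plus CSV tables (pairing tests, per-scheme median
#' D, relative range, age contrasts) and the representative pairings used,
#' for audit.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- report$pairing_tests
  readr::write_csv(
    dplyr::mutate(pt, p_chrom = vapply(.data$p_chrom, function(p)
      paste(signif(p, 6), collapse = ";"), character(1))),
    file.path(dir, "pairing_tests.csv"))
  readr::write_csv(report$scheme_median_d, file.path(dir, "scheme_median_d.csv"))
  readr::write_csv(report$relative_range, file.path(dir, "relative_range.csv"))
  if (!is.null(report$age_contrast$parameters)) {
    readr::write_csv(report$age_contrast$parameters$per_chromosome,
                     file.path(dir, "age_contrast_per_chromosome.csv"))
  }
  pairings <- attr(pt, "pairings")
  audit <- dplyr::bind_rows(lapply(names(pairings), function(param) {
    dplyr::bind_rows(lapply(names(pairings[[param]]), function(s) {
      dplyr::mutate(pairings[[param]][[s]][c("rep", "a", "b")],
                    scheme = s, param = param)
    }))
  }))
  readr::write_csv(audit, file.path(dir, "pairings_used.csv"))
  summary <- list(
    n_fits = report$n_fits, n_samples = report$n_samples, seed = report$seed,
    icc = report$icc,
    correlations = report$correlations,
    age_combined = if (is.null(report$age_contrast$parameters)) NULL else c(
      stats::setNames(report$age_contrast$parameters$combined$p_combined,
                      report$age_contrast$parameters$combined$param),
      var_explained = report$age_contrast$variance_explained$combined$p_combined
    )
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Preprocess a beta-value matrix into residual tracks
#'
#' Chains the standard preprocessing: logit2 transform to M values,
#' call-rate filtering, population mean/variance normalization and the
#' per-(sample, chromosome) split. Input matrices are assumed to be
#' probe-type (design I/II) normalized already.
#'
#' @param matrix A beta-scale [meth_matrix()].
#' @param manifest A probe manifest tibble.
#' @param min_rate Call-rate threshold (default 0.95).
#' @param min_sites Minimal sites per track (default 50).
#' @return A track tibble as from [split_by_chromosome()].
#' @export
preprocess_methylation <- function(matrix, manifest, min_rate = 0.95,
                                   min_sites = 50) {
  matrix |>
    beta_to_m() |>
    call_rate_filter(min_rate = min_rate) |>
    population_normalize() |>
    split_by_chromosome(manifest, min_sites = min_sites)
}

#' Expected number of model fits for a cohort
#'
#' Bookkeeping contract of the full pipeline: one dependency-model fit per
#' sample and autosome.
#'
#' @param n_samples Number of samples.
#' @param n_chromosomes Number of autosomes fitted (default 22).
#' @return Integer count.
#' @examples
#' expected_model_count(1611)  # 35442
#' @export
expected_model_count <- function(n_samples, n_chromosomes = 22L) {
  stopifnot(n_samples >= 0, n_chromosomes >= 0)
  as.integer(n_samples) * as.integer(n_chromosomes)
}
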