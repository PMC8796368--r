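#' Per-individual consistency of the dependency parameters
#'
#' Boxplots of the posterior-mean marginal sd (sigma) and range across
#' chromosomes for a subset of individuals: box size shows
#' within-individual (cross-chromosome) spread, box-to-box variation shows
#' between-individual differences.
#'
#' @param fits Parameter table from [fit_cohort()].
#' @param n_individuals Number of individuals to display (default 40,
#'   sampled deterministically by sorted sample id).
#' @return A ggplot object.
#' @export
plot_parameter_consistency <- function(fits, n_individuals = 40) {
  ids <- sort(unique(fits$sample_id))
  ids <- ids[seq_len(min(n_individuals, length(ids)))]
  dat <- fits[fits$sample_id %in% ids, ] |>
    dplyr::select("sample_id", "chrom", "sigma", "range_bp") |>
    tidyr::pivot_longer(c("sigma", "range_bp"), names_to = "parameter")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "individual", y = "posterior mean (across chromosomes)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Relative range per chromosome
#'
#' Boxplot of each individual's range estimates divided by their median
#' across chromosomes; the display is clipped to [0, 3] (analysis values
#' are not).
#'
#' @param fits Parameter table from [fit_cohort()].
#' @return A ggplot object.
#' @export
plot_relative_range <- function(fits) {
  rel <- relative_range(fits, summarize = FALSE)
  ggplot2::ggplot(rel, ggplot2::aes(x = factor(.data$chrom), y = .data$rel_range)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 1, color = "red", linewidth = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 3)) +
    ggplot2::labs(x = "chromosome", y = "relative range") +
    ggplot2::theme_minimal()
}

#' Dependency parameters colored by conversion plate
#'
#' Scatter of posterior-mean log(kappa) against log(tau) per fit, colored
#' by plate, which makes plate-level shifts (and an outlying plate)
#' directly visible.
#'
#' @param fits Parameter table from [fit_cohort()].
#' @param sheet Sample sheet tibble.
#' @param highlight Optional character vector of plate ids to emphasize.
#' @return A ggplot object.
#' @export
plot_dependency_scatter <- function(fits, sheet, highlight = NULL) {
  dat <- dplyr::left_join(fits, sheet[c("sample_id", "plate")], by = "sample_id")
  if (!is.null(highlight)) {
    dat$plate <- ifelse(dat$plate %in% highlight, dat$plate, "other")
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$post_mean_logtau,
                                    y = .data$post_mean_logkappa,
                                    color = .data$plate)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::labs(x = "posterior mean log(tau)", y = "posterior mean log(kappa)",
                  color = "plate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a `cohort_report` shows the relative-range profile with
#' the per-chromosome medians; on a `chromosome_fit` it shows the marginal
#' posterior grid of (log tau, log kappa).
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  ggplot2::ggplot(object$relative_range,
                  ggplot2::aes(x = factor(.data$chrom), y = .data$rel_range_median)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, color = "red", linewidth = 0.3) +
    ggplot2::labs(x = "chromosome", y = "median relative range") +
    ggplot2::theme_minimal()
}
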