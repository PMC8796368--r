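#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dependency-model fit
#'
#' @param x A `chromosome_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error` where available).
#' @method tidy chromosome_fit
#' @export
tidy.chromosome_fit <- function(x, ...) {
  tibble::tibble(
    term = c("logtau", "logkappa", "beta", "sigma0sq", "range_bp", "sigma"),
    estimate = c(x$post_mean_logtau, x$post_mean_logkappa, x$beta,
                 x$sigma0sq, x$range_bp, x$sigma),
    std.error = c(x$post_sd_logtau, x$post_sd_logkappa, NA, NA, NA, NA)
  )
}

#' @rdname tidy.chromosome_fit
#' @method tidy plain_fit
#' @export
tidy.plain_fit <- function(x, ...) {
  tibble::tibble(
    term = c("beta", "sigma0sq"),
    estimate = c(x$beta, x$sigma0sq),
    std.error = c(NA_real_, NA_real_)
  )
}

#' One-row fit summary
#'
#' @param x A `chromosome_fit` or `plain_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample/chromosome ids, `n_sites`, `dic`,
#'   `p_d`, `log_evidence` (and `boundary_flag` for dependency fits).
#' @export
glance.chromosome_fit <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, chrom = x$chrom, n_sites = x$n_sites,
    model = x$model, dic = x$dic, p_d = x$pd,
    log_evidence = x$log_evidence, boundary_flag = x$boundary_flag
  )
}

#' @rdname glance.chromosome_fit
#' @method glance plain_fit
#' @export
glance.plain_fit <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, chrom = x$chrom, n_sites = x$n_sites,
    model = x$model, dic = x$dic, p_d = x$pd, log_evidence = x$log_evidence
  )
}
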