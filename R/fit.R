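#' Residual track for one sample on one chromosome
#'
#' A `chromosome_track` holds the population-normalized methylation
#' residuals of a single sample at the sorted CpG positions of one
#' chromosome — the unit of data the dependency model is fitted to.
#'
#' @param positions Strictly increasing base-pair positions.
#' @param residuals Numeric residuals, same length as `positions`.
#' @param sample_id,chrom Optional identifiers carried into fit output.
#' @return An object of class `chromosome_track`.
#' @export
chromosome_track <- function(positions, residuals, sample_id = NA_character_,
                             chrom = NA_integer_) {
  stopifnot(is.numeric(positions), is.numeric(residuals))
  if (length(positions) != length(residuals)) {
    stop("`positions` and `residuals` must have equal length")
  }
  if (length(positions) > 1 && is.unsorted(positions, strictly = TRUE)) {
    stop("`positions` must be strictly increasing")
  }
  if (any(!is.finite(positions)) || any(!is.finite(residuals))) {
    stop("positions and residuals must be finite")
  }
  structure(
    list(positions = as.double(positions), residuals = as.double(residuals),
         sample_id = sample_id, chrom = chrom),
    class = "chromosome_track"
  )
}

#' @export
print.chromosome_track <- function(x, ...) {
  cat(sprintf("Chromosome track: sample %s, chr %s, %d sites [%s-%s bp]\n",
              x$sample_id, x$chrom, length(x$positions),
              format(min(x$positions)), format(max(x$positions))))
  invisible(x)
}

#' Quadrature-grid settings for hyperparameter inference
#'
#' @param n_nodes Nodes per grid dimension (default 11).
#' @param span_sd Half-width of each axis in approximate posterior sds
#'   (default 4). Under `strategy = "prior"` the half-width is in prior sds.
#' @param strategy `"adaptive"` (default) centers the grid at the posterior
#'   mode with axis scales from the numerical Hessian; `"prior"` spans the
#'   prior mean plus/minus `span_sd` prior sds for log tau and log kappa and
#'   a data-adaptive span for the log noise precision.
#' @param boundary_threshold Maximal tolerated posterior mass on the outer
#'   grid shell before the grid is widened and the fit re-run (default 0.05).
#' @param max_retries Number of widening retries (default 2).
#' @param transform `"mean_log"` (default) derives range and sigma from the
#'   posterior means of log kappa and log tau; `"node_mean"` averages the
#'   node-wise transformed values instead.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(n_nodes = 11, span_sd = 4,
                        strategy = c("adaptive", "prior"),
                        boundary_threshold = 0.05, max_retries = 2,
                        transform = c("mean_log", "node_mean")) {
  stopifnot(n_nodes >= 3, span_sd > 0, boundary_threshold > 0, max_retries >= 0)
  structure(
    list(n_nodes = as.integer(n_nodes), span_sd = span_sd,
         strategy = match.arg(strategy),
         boundary_threshold = boundary_threshold,
         max_retries = as.integer(max_retries),
         transform = match.arg(transform)),
    class = "grid_config"
  )
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log prior density over theta = (log tau, log kappa, log noise precision);
# the Gamma prior on the noise precision carries its log-scale Jacobian.
log_hyperprior <- function(logtau, logkappa, lognoiseprec, priors) {
  dnorm(logtau, priors$logtau_mean, 1 / sqrt(priors$logtau_precision), log = TRUE) +
    dnorm(logkappa, priors$logkappa_mean, 1 / sqrt(priors$logkappa_precision), log = TRUE) +
    priors$noise_shape * lognoiseprec - priors$noise_rate * exp(lognoiseprec) +
    priors$noise_shape * log(priors$noise_rate) - lgamma(priors$noise_shape)
}

#' Log marginal likelihood of a residual track
#'
#' Computes \eqn{\log p(y \mid \theta)} for the dependency model with the
#' latent field and the intercept integrated out analytically:
#' \eqn{y \mid \theta \sim N(\beta_0 1, \sigma^2 e^{-\kappa \Delta} +
#' \sigma_0^2 I + v_\beta 1 1^T)}. The computation uses the Markov
#' (state-space) representation of the exponential field and runs in O(n);
#' no dense matrix is formed.
#'
#' @param track A [chromosome_track()].
#' @param theta Numeric vector `c(logtau, logkappa, log_noise_precision)`,
#'   or a 3-column matrix of such rows (one value returned per row).
#' @param priors A [default_priors()] object (supplies the intercept prior).
#' @return Log marginal likelihood value(s).
#' @export
log_marginal_likelihood <- function(track, theta, priors = default_priors()) {
  stopifnot(inherits(track, "chromosome_track"))
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != 3) stop("`theta` must have 3 columns (logtau, logkappa, log noise precision)")
  if (any(!is.finite(theta))) stop("`theta` must be finite")
  tau <- exp(theta[, 1]); kappa <- exp(theta[, 2])
  sigma2 <- 1 / (2 * kappa * tau^2)          # lambda = 0.5 marginal variance
  noise_var <- exp(-theta[, 3])
  out <- cpp_ou_loglik(track$positions, track$residuals,
                       sigma2, kappa, noise_var,
                       priors$beta_mean, priors$beta_variance)
  if (nrow(theta) == 1) out[[1]] else out
}

# Posterior mode and curvature of log p(theta | y); used to place the grid.
find_mode <- function(track, priors) {
  n <- length(track$positions)
  vy <- if (n >= 2) stats::var(track$residuals) else 1
  if (!is.finite(vy) || vy <= 0) vy <- 1
  kappa0 <- exp(priors$logkappa_mean)
  tau0 <- tau_from_sigma_kappa(sqrt(max(vy / 2, 1e-8)), kappa0)
  init <- c(log(tau0), priors$logkappa_mean, log(2 / vy))
  negpost <- function(th) {
    -(log_marginal_likelihood(track, th, priors) +
        log_hyperprior(th[1], th[2], th[3], priors))
  }
  if (n == 0) {
    # prior-only limit: mode and curvature are those of the prior
    mode <- c(priors$logtau_mean, priors$logkappa_mean,
              log(priors$noise_shape / priors$noise_rate))
    sds <- c(1 / sqrt(priors$logtau_precision), 1 / sqrt(priors$logkappa_precision),
             sqrt(trigamma(priors$noise_shape)))
    return(list(mode = mode, sds = sds))
  }
  opt <- stats::optim(init, negpost, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 200, reltol = 1e-10))
  sds <- rep(NA_real_, 3)
  ev <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(ev, "try-error")) {
    d <- diag(ev)
    ok <- is.finite(d) & d > 0
    sds[ok] <- sqrt(d[ok])
  }
  # fall back to prior scales where the curvature is unusable
  prior_sds <- c(1 / sqrt(priors$logtau_precision),
                 1 / sqrt(priors$logkappa_precision), 2)
  sds[!is.finite(sds) | sds <= 0] <- prior_sds[!is.finite(sds) | sds <= 0]
  sds <- pmin(sds, prior_sds)
  list(mode = opt$par, sds = sds)
}

build_axes <- function(track, priors, config, widen = 1) {
  if (config$strategy == "adaptive") {
    mc <- find_mode(track, priors)
    centers <- mc$mode
    half <- config$span_sd * mc$sds * widen
  } else {
    n <- length(track$positions)
    vy <- if (n >= 2) stats::var(track$residuals) else 1
    if (!is.finite(vy) || vy <= 0) vy <- 1
    centers <- c(priors$logtau_mean, priors$logkappa_mean, log(1 / vy))
    half <- c(config$span_sd / sqrt(priors$logtau_precision),
              config$span_sd / sqrt(priors$logkappa_precision), 6) * widen
  }
  lapply(1:3, function(k) {
    seq(centers[k] - half[k], centers[k] + half[k], length.out = config$n_nodes)
  })
}

#' Fit the dependency model to one track
#'
#' Runs full Bayesian inference for the spatial dependency model on a
#' single residual track: the latent field and intercept are marginalized
#' exactly (Kalman filter on the Markov representation), and the posterior
#' over the three hyperparameters (log tau, log kappa, log noise precision)
#' is evaluated on a quadrature grid normalized by log-sum-exp. Posterior
#' means and sds of log tau and log kappa, the posterior-mean intercept and
#' noise variance, the derived range and marginal sd, the DIC and the log
#' model evidence are returned.
#'
#' If more than `boundary_threshold` of the posterior mass sits on the
#' outer grid shell, the grid is widened and the fit rerun (up to
#' `max_retries` times); a persisting overflow sets `boundary_flag`.
#'
#' @param track A [chromosome_track()]. A track with zero sites yields the
#'   prior-only posterior (useful for checking the no-data limit).
#' @param priors A [default_priors()] object.
#' @param config A [grid_config()].
#' @return An object of class `chromosome_fit`.
#' @export
fit_chromosome <- function(track, priors = default_priors(), config = grid_config()) {
  stopifnot(inherits(track, "chromosome_track"), inherits(priors, "matern_priors"))
  n <- length(track$positions)
  widen <- 1
  for (attempt in 0:config$max_retries) {
    axes <- build_axes(track, priors, config, widen = widen)
    nodes <- expand.grid(logtau = axes[[1]], logkappa = axes[[2]],
                         lognoiseprec = axes[[3]], KEEP.OUT.ATTRS = FALSE)
    lp <- log_marginal_likelihood(track, as.matrix(nodes), priors) +
      log_hyperprior(nodes$logtau, nodes$logkappa, nodes$lognoiseprec, priors)
    lse <- log_sum_exp(lp)
    w <- exp(lp - lse)
    on_edge <- nodes$logtau %in% range(axes[[1]]) |
      nodes$logkappa %in% range(axes[[2]]) |
      nodes$lognoiseprec %in% range(axes[[3]])
    boundary_mass <- sum(w[on_edge])
    if (boundary_mass <= config$boundary_threshold || attempt == config$max_retries) break
    widen <- widen * 1.5
  }
  boundary_flag <- boundary_mass > config$boundary_threshold
  spacing <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  log_evidence <- lse + sum(log(spacing))

  pm_logtau <- sum(w * nodes$logtau)
  pm_logkappa <- sum(w * nodes$logkappa)
  pm_lognoiseprec <- sum(w * nodes$lognoiseprec)
  psd_logtau <- sqrt(max(sum(w * (nodes$logtau - pm_logtau)^2), 0))
  psd_logkappa <- sqrt(max(sum(w * (nodes$logkappa - pm_logkappa)^2), 0))

  tau_n <- exp(nodes$logtau); kappa_n <- exp(nodes$logkappa)
  sigma2_n <- 1 / (2 * kappa_n * tau_n^2)
  noise_n <- exp(-nodes$lognoiseprec)
  sigma0sq <- sum(w * noise_n)

  if (config$transform == "mean_log") {
    range_bp <- range_from_kappa(exp(pm_logkappa))
    sigma <- sigma_from_tau_kappa(exp(pm_logtau), exp(pm_logkappa))
  } else {
    range_bp <- sum(w * range_from_kappa(kappa_n))
    sigma <- sum(w * sqrt(sigma2_n))
  }

  if (n > 0) {
    # Field-marginal deviance pieces: C = sigma^2 exp(-kappa dp) + sigma0^2 I
    b0 <- priors$beta_mean; v0 <- priors$beta_variance
    qf <- cpp_ou_quad(track$positions, track$residuals, sigma2_n, kappa_n, noise_n)
    q_n <- qf[, "oCo"] + 1 / v0
    mbeta_n <- (qf[, "oCy"] + b0 / v0) / q_n
    beta <- sum(w * mbeta_n)
    edev_n <- n * log(2 * pi) + qf[, "logdet"] +
      (qf[, "yCy"] - 2 * mbeta_n * qf[, "oCy"] + mbeta_n^2 * qf[, "oCo"]) +
      qf[, "oCo"] / q_n
    dbar <- sum(w * edev_n)
    # plug-in deviance at the posterior mode (max-weight node); with
    # ridge-shaped posteriors the coordinate-wise mean can sit off the
    # ridge and misstate the plug-in fit, so the modal node is used
    jhat <- which.max(w)
    dhat <- unname(n * log(2 * pi) + qf[jhat, "logdet"] +
      (qf[jhat, "yCy"] - 2 * mbeta_n[jhat] * qf[jhat, "oCy"] +
         mbeta_n[jhat]^2 * qf[jhat, "oCo"]))
    pd <- dbar - dhat
    dic <- dbar + pd
  } else {
    beta <- priors$beta_mean
    dbar <- dhat <- pd <- dic <- NA_real_
  }

  structure(
    list(
      sample_id = track$sample_id, chrom = track$chrom, n_sites = n,
      post_mean_logtau = pm_logtau, post_sd_logtau = psd_logtau,
      post_mean_logkappa = pm_logkappa, post_sd_logkappa = psd_logkappa,
      beta = beta, sigma0sq = sigma0sq,
      range_bp = range_bp, sigma = sigma,
      dic = dic, dbar = dbar, pd = pd,
      log_evidence = log_evidence,
      grid = list(axes = axes, boundary_mass = boundary_mass,
                  widen = widen, n_nodes = config$n_nodes),
      boundary_flag = boundary_flag,
      model = "dependency"
    ),
    class = "chromosome_fit"
  )
}

#' @export
print.chromosome_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Dependency-model fit (sample %s, chr %s, n = %d):\n",
           "  log(tau)   %.3f (sd %.3f)    log(kappa) %.3f (sd %.3f)\n",
           "  range %.0f bp   sigma %.3f   sigma0^2 %.4f   beta %.4f\n",
           "  DIC %.1f (p_D %.1f)   log evidence %.1f%s\n"),
    x$sample_id, x$chrom, x$n_sites,
    x$post_mean_logtau, x$post_sd_logtau, x$post_mean_logkappa, x$post_sd_logkappa,
    x$range_bp, x$sigma, x$sigma0sq, x$beta, x$dic, x$pd, x$log_evidence,
    if (isTRUE(x$boundary_flag)) "   [boundary mass exceeded]" else ""
  ))
  invisible(x)
}

#' Fit the independence (plain) model to one track
#'
#' The plain model drops the latent field: \eqn{y_i \sim N(\beta,
#' \sigma_0^2)} iid, with the same intercept and noise priors as the
#' dependency model. The intercept is conjugate and integrated exactly; the
#' posterior over the log noise precision is evaluated on an adaptive 1-D
#' quadrature grid. Serves as the DIC baseline.
#'
#' @param track A [chromosome_track()] (positions are ignored by the model).
#' @param priors A [default_priors()] object.
#' @param n_nodes Quadrature nodes over log noise precision (default 61).
#' @return An object of class `plain_fit`.
#' @export
fit_plain <- function(track, priors = default_priors(), n_nodes = 61) {
  stopifnot(inherits(track, "chromosome_track"))
  y <- track$residuals
  n <- length(y)
  if (n < 1) stop("plain fit requires at least one observation")
  b0 <- priors$beta_mean; v0 <- priors$beta_variance
  d <- y - b0; S <- sum(d^2); sd1 <- sum(d)
  loglik <- function(lnp) {
    R <- exp(-lnp)
    logdet <- n * log(R) + log1p(n * v0 / R)
    quad <- S / R - v0 * sd1^2 / (R * (R + n * v0))
    -0.5 * (n * log(2 * pi) + logdet + quad)
  }
  logpost <- function(lnp) {
    loglik(lnp) + priors$noise_shape * lnp - priors$noise_rate * exp(lnp) +
      priors$noise_shape * log(priors$noise_rate) - lgamma(priors$noise_shape)
  }
  vy <- if (n >= 2) stats::var(y) else 1
  if (!is.finite(vy) || vy <= 0) vy <- 1
  opt <- stats::optimize(function(t) -logpost(t),
                         interval = log(1 / vy) + c(-12, 12))
  mode <- opt$minimum
  h <- 1e-3
  curv <- -(logpost(mode + h) - 2 * logpost(mode) + logpost(mode - h)) / h^2
  sdv <- if (is.finite(curv) && curv > 0) 1 / sqrt(curv) else 2
  axis <- seq(mode - 6 * sdv, mode + 6 * sdv, length.out = n_nodes)
  lp <- vapply(axis, logpost, numeric(1))
  lse <- log_sum_exp(lp)
  w <- exp(lp - lse)
  log_evidence <- lse + log(axis[2] - axis[1])

  R_n <- exp(-axis)
  q_n <- n / R_n + 1 / v0
  mbeta_n <- (sum(y) / R_n + b0 / v0) / q_n
  beta <- sum(w * mbeta_n)
  sigma0sq <- sum(w * R_n)
  edev <- vapply(seq_along(axis), function(j) {
    n * log(2 * pi * R_n[j]) + (sum((y - mbeta_n[j])^2) + n / q_n[j]) / R_n[j]
  }, numeric(1))
  dbar <- sum(w * edev)
  jhat <- which.max(w)            # plug-in at the posterior modal node
  dhat <- n * log(2 * pi * R_n[jhat]) + sum((y - mbeta_n[jhat])^2) / R_n[jhat]
  pd <- dbar - dhat
  structure(
    list(sample_id = track$sample_id, chrom = track$chrom, n_sites = n,
         beta = beta, sigma0sq = sigma0sq,
         dic = dbar + pd, dbar = dbar, pd = pd,
         log_evidence = log_evidence, model = "plain"),
    class = "plain_fit"
  )
}

#' @export
print.plain_fit <- function(x, ...) {
  cat(sprintf(
    "Plain-model fit (sample %s, chr %s, n = %d): beta %.4f, sigma0^2 %.4f, DIC %.1f (p_D %.2f)\n",
    x$sample_id, x$chrom, x$n_sites, x$beta, x$sigma0sq, x$dic, x$pd
  ))
  invisible(x)
}

#' DIC components of a fitted model
#'
#' The deviance information criterion is computed on the observation model
#' with the latent field integrated out, so the deviance parameters are the
#' intercept and the hyperparameters: for the dependency model
#' \eqn{D(\beta, \theta) = -2 \log N(y; \beta 1, \sigma^2 e^{-\kappa\Delta}
#' + \sigma_0^2 I)}, for the plain model
#' \eqn{D(\beta, \sigma_0^2) = -2 \sum \log N(y_i; \beta, \sigma_0^2)}.
#' \eqn{\bar D} is the posterior expectation of the deviance,
#' \eqn{p_D = \bar D - D} at the posterior mode (the modal quadrature
#' node; robust where a ridge-shaped posterior makes the coordinate-wise
#' mean a poor point estimate), and
#' \eqn{DIC = \bar D + p_D}. Treating the field as part of the stochastic
#' model rather than as parameters keeps the dependency-vs-plain
#' comparison well behaved when the noise/field variance split is weakly
#' identified (on null data both deviances coincide along that ridge).
#'
#' @param fit A `chromosome_fit` or `plain_fit`.
#' @return A list with `dic`, `dbar` (mean deviance) and `pd`
#'   (effective number of parameters).
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "chromosome_fit") || inherits(fit, "plain_fit"))
  list(dic = fit$dic, dbar = fit$dbar, pd = fit$pd)
}

#' Compare the dependency and plain models by DIC
#'
#' @param dep A `chromosome_fit`.
#' @param plain A `plain_fit` on the same track.
#' @param threshold DIC difference regarded as decisive (default 4).
#' @return A list with `delta_dic = DIC_plain - DIC_dep` and `favored`
#'   (`"dependency"`, `"plain"` or `"indeterminate"`).
#' @export
compare_models <- function(dep, plain, threshold = 4) {
  stopifnot(inherits(dep, "chromosome_fit"), inherits(plain, "plain_fit"))
  if (dep$n_sites != plain$n_sites ||
      !identical(dep$sample_id, plain$sample_id) ||
      !identical(dep$chrom, plain$chrom)) {
    stop("`dep` and `plain` must be fits of the same track")
  }
  delta <- plain$dic - dep$dic
  favored <- if (delta > threshold) "dependency"
  else if (delta < -threshold) "plain"
  else "indeterminate"
  list(delta_dic = delta, favored = favored)
}

#' Proportion of residual variance explained by the spatial field
#'
#' One minus the ratio of the dependency model's noise variance to the
#' plain model's noise variance. Slightly negative values can occur on
#' null data and are not clipped.
#'
#' @param dep A `chromosome_fit`.
#' @param plain A `plain_fit` on the same track.
#' @return A scalar fraction.
#' @export
variance_explained <- function(dep, plain) {
  stopifnot(inherits(dep, "chromosome_fit"), inherits(plain, "plain_fit"))
  if (plain$sigma0sq <= 0) stop("plain-model noise variance is zero")
  1 - dep$sigma0sq / plain$sigma0sq
}

#' Fit both models to every track of a cohort
#'
#' Maps [fit_chromosome()] and [fit_plain()] over a track table (as
#' produced by [split_by_chromosome()]) and assembles the per-track
#' parameter table that all cohort statistics consume. Individual track
#' failures are caught and reported; the run aborts only if more than
#' `max_fail_frac` of the tracks fail.
#'
#' @param tracks A tibble with columns `sample_id`, `chrom`, `track`
#'   (list-column of [chromosome_track()] objects).
#' @param priors A [default_priors()] object.
#' @param config A [grid_config()].
#' @param threshold DIC decision threshold passed to [compare_models()].
#' @param max_fail_frac Maximal tolerated fraction of failed tracks
#'   (default 0.1).
#' @param verbose Print progress every 200 tracks.
#' @return A tibble with one row per (sample, chromosome): `sample_id`,
#'   `chrom`, `n_sites`, `post_mean_logtau`, `post_sd_logtau`,
#'   `post_mean_logkappa`, `post_sd_logkappa`, `beta`, `sigma0sq`,
#'   `range_bp`, `sigma`, `dic_dep`, `dic_plain`, `delta_dic`, `favored`,
#'   `var_explained`, `boundary_flag`.
#' @export
fit_cohort <- function(tracks, priors = default_priors(), config = grid_config(),
                       threshold = 4, max_fail_frac = 0.1, verbose = FALSE) {
  stopifnot(is.data.frame(tracks), all(c("sample_id", "chrom", "track") %in% names(tracks)))
  rows <- vector("list", nrow(tracks))
  failures <- character(0)
  for (i in seq_len(nrow(tracks))) {
    tr <- tracks$track[[i]]
    res <- tryCatch({
      dep <- fit_chromosome(tr, priors, config)
      pl <- fit_plain(tr, priors)
      cmp <- compare_models(dep, pl, threshold)
      tibble::tibble(
        sample_id = tracks$sample_id[i], chrom = tracks$chrom[i],
        n_sites = dep$n_sites,
        post_mean_logtau = dep$post_mean_logtau, post_sd_logtau = dep$post_sd_logtau,
        post_mean_logkappa = dep$post_mean_logkappa, post_sd_logkappa = dep$post_sd_logkappa,
        beta = dep$beta, sigma0sq = dep$sigma0sq,
        range_bp = dep$range_bp, sigma = dep$sigma,
        dic_dep = dep$dic, dic_plain = pl$dic, delta_dic = cmp$delta_dic,
        favored = cmp$favored,
        var_explained = variance_explained(dep, pl),
        boundary_flag = dep$boundary_flag
      )
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s/chr%s: %s", tracks$sample_id[i],
                                       tracks$chrom[i], conditionMessage(e)))
      NULL
    })
    rows[[i]] <- res
    if (verbose && i %% 200 == 0) message(sprintf("fitted %d/%d tracks", i, nrow(tracks)))
  }
  if (length(failures) > max_fail_frac * nrow(tracks)) {
    stop(sprintf("%d of %d tracks failed to fit; first error: %s",
                 length(failures), nrow(tracks), failures[1]))
  }
  if (length(failures) > 0) {
    warning(sprintf("%d track(s) failed and were dropped", length(failures)))
  }
  dplyr::bind_rows(rows)
}
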