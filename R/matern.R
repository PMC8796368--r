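#' Matern dependency parameterization
#'
#' A `matern_spec` bundles the three parameters of the stationary 1-D Matern
#' Gaussian field used to model co-methylation: the smoothness `lambda`
#' (fixed at 0.5 throughout the pipeline, giving exponential decay), the
#' inverse-range scale `kappa` (units 1/bp) and the precision-like scale
#' `tau`. Two derived quantities are carried along: the range
#' `r = sqrt(8 lambda) / kappa`, the distance at which the spatial
#' correlation has dropped to roughly 0.1, and the marginal standard
#' deviation `sigma` of the field.
#'
#' @param kappa Inverse-range parameter, in 1/bp. Must be positive. Smaller
#'   values mean longer-ranged dependence.
#' @param tau Precision-like scale controlling the marginal variance
#'   (larger `tau`, less variance). Must be positive.
#' @param lambda Matern smoothness; `0.5` (the default) gives the
#'   exponential covariance \eqn{\sigma^2 e^{-\kappa d}}.
#' @return An object of class `matern_spec`: a list with elements `kappa`,
#'   `tau`, `lambda`, `range_bp` and `sigma`.
#' @examples
#' sp <- matern_spec(kappa = 2 / 3000, tau = sqrt(750))
#' sp$range_bp   # 3000
#' sp$sigma      # 1
#' @export
matern_spec <- function(kappa, tau, lambda = 0.5) {
  stopifnot(is.numeric(kappa), is.numeric(tau), is.numeric(lambda),
            length(kappa) == 1, length(tau) == 1, length(lambda) == 1)
  if (!is.finite(kappa) || kappa <= 0) stop("`kappa` must be finite and > 0")
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be finite and > 0")
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be finite and > 0")
  structure(
    list(
      kappa = kappa, tau = tau, lambda = lambda,
      range_bp = range_from_kappa(kappa, lambda),
      sigma = sigma_from_tau_kappa(tau, kappa, lambda)
    ),
    class = "matern_spec"
  )
}

#' @export
print.matern_spec <- function(x, ...) {
  cat(sprintf(
    "Matern field spec (lambda = %g):\n  kappa = %g /bp   tau = %g\n  range = %g bp   sigma = %g\n",
    x$lambda, x$kappa, x$tau, x$range_bp, x$sigma
  ))
  invisible(x)
}

#' Matern covariance function in one dimension
#'
#' Evaluates \eqn{C(d) = \sigma^2 / (\Gamma(\lambda) 2^{\lambda-1})
#' (\kappa d)^\lambda K_\lambda(\kappa d)} at base-pair distance `d`,
#' where \eqn{K_\lambda} is the modified Bessel function of the second kind.
#' At `d = 0` the covariance is the marginal variance \eqn{\sigma^2}. For
#' `lambda = 0.5` this reduces to the exponential covariance
#' \eqn{\sigma^2 e^{-\kappa d}}, the form used everywhere in the fitting
#' pipeline; other smoothness values are supported for validation.
#'
#' @param distance_bp Non-negative distance(s) in base pairs (vectorized).
#' @param spec A [matern_spec()].
#' @return Covariance value(s), same length as `distance_bp`.
#' @export
matern_covariance <- function(distance_bp, spec) {
  stopifnot(inherits(spec, "matern_spec"), is.numeric(distance_bp))
  if (any(!is.finite(distance_bp)) || any(distance_bp < 0)) {
    stop("`distance_bp` must be finite and >= 0")
  }
  s2 <- spec$sigma^2
  lam <- spec$lambda
  u <- spec$kappa * distance_bp
  out <- rep(s2, length(u))
  pos <- u > 0
  if (any(pos)) {
    up <- u[pos]
    out[pos] <- s2 / (gamma(lam) * 2^(lam - 1)) * up^lam * besselK(up, lam)
  }
  out
}

#' Range from the inverse-range parameter (and back)
#'
#' `range_from_kappa()` returns \eqn{r = \sqrt{8\lambda}/\kappa}, the
#' distance at which the Matern correlation is close to 0.1;
#' `kappa_from_range()` is its inverse.
#'
#' @param kappa Inverse-range parameter (1/bp), positive.
#' @param range_bp Range in base pairs, positive.
#' @param lambda Matern smoothness, positive.
#' @return Range in bp, or `kappa` in 1/bp.
#' @export
range_from_kappa <- function(kappa, lambda = 0.5) {
  if (any(!is.finite(kappa)) || any(kappa <= 0)) stop("`kappa` must be > 0")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("`lambda` must be > 0")
  sqrt(8 * lambda) / kappa
}

#' @rdname range_from_kappa
#' @export
kappa_from_range <- function(range_bp, lambda = 0.5) {
  if (any(!is.finite(range_bp)) || any(range_bp <= 0)) stop("`range_bp` must be > 0")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("`lambda` must be > 0")
  sqrt(8 * lambda) / range_bp
}

#' Marginal standard deviation from (tau, kappa) and back
#'
#' The marginal variance of the field and the precision-like scale `tau`
#' are inversely related:
#' \deqn{\sigma^2 = \Gamma(\lambda) / (\Gamma(\lambda + 1/2) (4\pi)^{1/2}
#' \kappa^{2\lambda} \tau^2)}
#' (the one-dimensional convention). For `lambda = 0.5` this simplifies to
#' \eqn{\sigma^2 = 1/(2 \kappa \tau^2)}. `tau_from_sigma_kappa()` inverts
#' the relation for `tau`.
#'
#' @param tau,kappa,lambda,sigma Positive scalars (vectorized over the
#'   first argument).
#' @return `sigma` (marginal sd) or `tau`.
#' @export
sigma_from_tau_kappa <- function(tau, kappa, lambda = 0.5) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("`tau` must be > 0")
  if (any(!is.finite(kappa)) || any(kappa <= 0)) stop("`kappa` must be > 0")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("`lambda` must be > 0")
  s2 <- gamma(lambda) / (gamma(lambda + 0.5) * sqrt(4 * pi) * kappa^(2 * lambda) * tau^2)
  sqrt(s2)
}

#' @rdname sigma_from_tau_kappa
#' @export
tau_from_sigma_kappa <- function(sigma, kappa, lambda = 0.5) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("`sigma` must be > 0")
  if (any(!is.finite(kappa)) || any(kappa <= 0)) stop("`kappa` must be > 0")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("`lambda` must be > 0")
  sqrt(gamma(lambda) / (gamma(lambda + 0.5) * sqrt(4 * pi) * kappa^(2 * lambda) * sigma^2))
}

#' Hyperparameter priors for the dependency model
#'
#' Builds the prior set used for every per-track fit: a vague Gaussian on the
#' intercept, a vague Gamma on the noise precision \eqn{1/\sigma_0^2}, and
#' Gaussians on log(tau) and log(kappa) whose means are calibrated so that
#' the prior field has range `range0` and marginal variance `sigma2_0`. With
#' the defaults (`range0 = 3000` bp, `sigma2_0 = 1`) the prior means are
#' `exp(logkappa_mean) = 2/3000 = 0.00067` and
#' `exp(logtau_mean) = sqrt(750) = 27.39`. The log-scale precisions of 0.05
#' (variance 20) keep both priors weak.
#'
#' @param range0 Prior range in bp (default 3000).
#' @param sigma2_0 Prior marginal variance of the field (default 1).
#' @param lambda Matern smoothness (default 0.5).
#' @param logtau_precision,logkappa_precision Gaussian precisions of the
#'   log-scale priors (default 0.05 each).
#' @param beta_mean,beta_variance Gaussian prior on the intercept
#'   (default N(0, 1e6)).
#' @param noise_shape,noise_rate Gamma prior on the noise precision
#'   (default Gamma(1, 5e-5)).
#' @return An object of class `matern_priors` (a list of the named fields).
#' @examples
#' pr <- default_priors()
#' exp(pr$logtau_mean)    # 27.39
#' exp(pr$logkappa_mean)  # 0.00067
#' @export
default_priors <- function(range0 = 3000, sigma2_0 = 1, lambda = 0.5,
                           logtau_precision = 0.05, logkappa_precision = 0.05,
                           beta_mean = 0, beta_variance = 1e6,
                           noise_shape = 1, noise_rate = 5e-5) {
  if (!is.finite(range0) || range0 <= 0) stop("`range0` must be > 0")
  if (!is.finite(sigma2_0) || sigma2_0 <= 0) stop("`sigma2_0` must be > 0")
  stopifnot(
    logtau_precision > 0, logkappa_precision > 0,
    beta_variance > 0, noise_shape > 0, noise_rate > 0
  )
  kappa_m <- kappa_from_range(range0, lambda)
  tau_m <- tau_from_sigma_kappa(sqrt(sigma2_0), kappa_m, lambda)
  structure(
    list(
      lambda = lambda,
      beta_mean = beta_mean, beta_variance = beta_variance,
      noise_shape = noise_shape, noise_rate = noise_rate,
      logtau_mean = log(tau_m), logtau_precision = logtau_precision,
      logkappa_mean = log(kappa_m), logkappa_precision = logkappa_precision
    ),
    class = "matern_priors"
  )
}

#' @export
print.matern_priors <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Dependency-model hyperpriors (lambda = %g):\n",
      "  beta ~ N(%g, %g)\n  1/sigma0^2 ~ Gamma(%g, %g)\n",
      "  log(tau) ~ N(%.4f, prec %g)   [tau_m = %.2f]\n",
      "  log(kappa) ~ N(%.4f, prec %g) [kappa_m = %.5f]\n"
    ),
    x$lambda, x$beta_mean, x$beta_variance, x$noise_shape, x$noise_rate,
    x$logtau_mean, x$logtau_precision, exp(x$logtau_mean),
    x$logkappa_mean, x$logkappa_precision, exp(x$logkappa_mean)
  ))
  invisible(x)
}

#' Markov (tridiagonal-precision) representation of the exponential field
#'
#' For `lambda = 0.5` the Matern field observed at sorted positions is a
#' Markov chain (an Ornstein-Uhlenbeck bridge structure), so its precision
#' matrix is tridiagonal and exactly invertible to the dense covariance
#' \eqn{\sigma^2 e^{-\kappa |p_i - p_j|}}. This is the representation the
#' likelihood code exploits; here it is exposed for inspection and testing.
#'
#' With lag correlations \eqn{\rho_i = e^{-\kappa (p_{i+1} - p_i)}} the
#' nonzero precision entries are
#' \eqn{Q_{i,i+1} = -\rho_i / (\sigma^2 (1 - \rho_i^2))} and
#' \eqn{Q_{ii} = 1/\sigma^2 (1/(1-\rho_{i-1}^2) + \rho_i^2/(1-\rho_i^2))}
#' (boundary terms drop the missing neighbor). The log-determinant is
#' available in closed form in O(n).
#'
#' @param positions Strictly increasing base-pair positions (length >= 1).
#' @param spec A [matern_spec()] with `lambda = 0.5`.
#' @return An object of class `ou_precision`: list with `diag`, `offdiag`
#'   (length n-1), `logdet`, `positions` and `spec`.
#' @export
markov_precision <- function(positions, spec) {
  stopifnot(inherits(spec, "matern_spec"), is.numeric(positions), length(positions) >= 1)
  if (spec$lambda != 0.5) {
    stop("the Markov representation exists only for lambda = 0.5 (exponential covariance)")
  }
  if (any(!is.finite(positions))) stop("positions must be finite")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing (sorted, no duplicates)")
  }
  n <- length(positions)
  s2 <- spec$sigma^2
  if (n == 1L) {
    return(structure(
      list(diag = 1 / s2, offdiag = numeric(0), logdet = -log(s2),
           positions = positions, spec = spec),
      class = "ou_precision"
    ))
  }
  rho <- exp(-spec$kappa * diff(positions))
  omr2 <- 1 - rho^2
  d <- numeric(n)
  d[1] <- 1 / omr2[1]
  d[n] <- 1 / omr2[n - 1]
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- 1 / omr2[i - 1] + rho[i]^2 / omr2[i]
  } else {
    d[1] <- 1 / omr2[1]
  }
  off <- -rho / omr2
  # det(Q) = prod of conditional precisions: (1/s2) * prod 1/(s2*(1-rho^2))
  logdet <- -n * log(s2) - sum(log(omr2))
  structure(
    list(diag = d / s2, offdiag = off / s2, logdet = logdet,
         positions = positions, spec = spec),
    class = "ou_precision"
  )
}

#' @export
print.ou_precision <- function(x, ...) {
  cat(sprintf("Tridiagonal OU precision: n = %d sites, logdet = %.4f\n",
              length(x$diag), x$logdet))
  invisible(x)
}

#' Dense matrix form of an `ou_precision` object
#'
#' @param x An `ou_precision` object.
#' @param ... Unused.
#' @return A dense n x n precision matrix.
#' @export
as.matrix.ou_precision <- function(x, ...) {
  n <- length(x$diag)
  Q <- diag(x$diag, n, n)
  if (n > 1) {
    idx <- seq_len(n - 1)
    Q[cbind(idx, idx + 1)] <- x$offdiag
    Q[cbind(idx + 1, idx)] <- x$offdiag
  }
  Q
}
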