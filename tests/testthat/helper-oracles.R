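# Independent oracles used across the suite. These deliberately avoid the
# package's O(n) Markov code paths: covariances are built densely and
# factorized with base chol().

dense_ou_cov <- function(pos, sigma2, kappa) {
  sigma2 * exp(-kappa * abs(outer(pos, pos, "-")))
}

# log N(y; b0*1, sigma2*exp(-kappa|dp|) + noise_var*I + v0*J)
dense_loglik <- function(pos, y, sigma2, kappa, noise_var, b0 = 0, v0 = 1e6) {
  n <- length(pos)
  C <- dense_ou_cov(pos, sigma2, kappa) + diag(noise_var, n) + v0
  L <- chol(C)
  z <- backsolve(L, y - b0, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# independent prior log-density over (logtau, logkappa, log noise precision)
oracle_log_prior <- function(th, priors) {
  ptau <- -0.5 * priors$logtau_precision * (th[1] - priors$logtau_mean)^2 +
    0.5 * log(priors$logtau_precision / (2 * pi))
  pkap <- -0.5 * priors$logkappa_precision * (th[2] - priors$logkappa_mean)^2 +
    0.5 * log(priors$logkappa_precision / (2 * pi))
  # Gamma on the precision, with log-scale Jacobian
  prec <- exp(th[3])
  pnoise <- stats::dgamma(prec, priors$noise_shape, priors$noise_rate, log = TRUE) + th[3]
  ptau + pkap + pnoise
}

# random-walk Metropolis over theta with the dense-likelihood oracle
mh_posterior_means <- function(pos, y, priors, n_iter = 15000, burn = 5000,
                               step = c(0.25, 0.4, 0.2), init = NULL, seed = 1) {
  set.seed(seed)
  logpost <- function(th) {
    tau <- exp(th[1]); kappa <- exp(th[2])
    dense_loglik(pos, y, 1 / (2 * kappa * tau^2), kappa, exp(-th[3]),
                 priors$beta_mean, priors$beta_variance) +
      oracle_log_prior(th, priors)
  }
  th <- if (is.null(init)) {
    c(priors$logtau_mean, priors$logkappa_mean, log(1 / stats::var(y)))
  } else init
  lp <- logpost(th)
  draws <- matrix(NA_real_, n_iter, 3)
  acc <- 0
  for (i in seq_len(n_iter)) {
    prop <- th + stats::rnorm(3) * step
    lp_prop <- logpost(prop)
    if (log(stats::runif(1)) < lp_prop - lp) {
      th <- prop; lp <- lp_prop; acc <- acc + 1
    }
    draws[i, ] <- th
  }
  list(means = colMeans(draws[(burn + 1):n_iter, , drop = FALSE]),
       accept = acc / n_iter)
}

# clustered positions reused by fitting tests
test_positions <- function(n, seed, island_gap = 60, bg_gap = 2500, p_island = 0.35) {
  set.seed(seed)
  gaps <- ifelse(stats::runif(n) < p_island,
                 stats::rexp(n, 1 / island_gap) + 10,
                 stats::rexp(n, 1 / bg_gap) + 100)
  cumsum(gaps) + 1e5
}

# default-scale dependency track for fitting tests
sim_test_track <- function(n, seed, range_bp = 3000, sigma2 = 0.75, sigma0 = 0.5) {
  pos <- test_positions(n, seed)
  kap <- kappa_from_range(range_bp)
  sp <- matern_spec(kap, tau_from_sigma_kappa(sqrt(sigma2), kap))
  y <- simulate_track(pos, sp, sigma0, seed = seed + 1)$y
  chromosome_track(pos, y)
}

# small beta-scale matrix fixture with ids
toy_beta_matrix <- function(nr = 3, nc = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(nr * nc, 0.1, 0.9), nr, nc,
              dimnames = list(sprintf("cg%03d", seq_len(nr)),
                              sprintf("S%02d", seq_len(nc))))
  meth_matrix(m, scale = "beta")
}
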