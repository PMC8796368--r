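test_that("spec derived quantities are exact and invertible", {
  sp <- matern_spec(kappa = 0.002, tau = 5, lambda = 0.5)
  expect_equal(sp$range_bp, sqrt(8 * 0.5) / 0.002)
  expect_equal(sp$sigma^2, 1 / (2 * 0.002 * 25))
  # round trip tau <-> sigma at 1e-12 relative, across lambdas
  for (lam in c(0.5, 1, 1.5)) {
    for (kap in c(1e-4, 0.002, 0.5)) {
      tau <- 3.7
      sig <- sigma_from_tau_kappa(tau, kap, lam)
      expect_equal(tau_from_sigma_kappa(sig, kap, lam), tau, tolerance = 1e-12)
    }
  }
  expect_error(matern_spec(-1, 1), "kappa")
  expect_error(matern_spec(1, 0), "tau")
})

test_that("matern covariance matches the exponential special case and Bessel formula", {
  sp <- matern_spec(kappa = 0.001, tau = tau_from_sigma_kappa(1, 0.001))
  expect_equal(matern_covariance(0, sp), sp$sigma^2)
  expect_equal(matern_covariance(1000, sp), exp(-1), tolerance = 1e-10)
  # general-lambda evaluation against a direct high-precision computation
  kap <- 0.002; lam <- 1.5
  tau <- tau_from_sigma_kappa(sqrt(2), kap, lam)
  sp2 <- matern_spec(kap, tau, lambda = lam)
  d <- 700
  u <- kap * d
  direct <- 2 / (gamma(lam) * 2^(lam - 1)) * u^lam * besselK(u, lam)
  expect_equal(matern_covariance(d, sp2), direct, tolerance = 1e-12)
  expect_error(matern_covariance(-5, sp), "distance")
})

test_that("covariance decreases in distance and in kappa", {
  d <- seq(0, 20000, by = 500)
  sp <- matern_spec(0.0007, 20)
  v <- matern_covariance(d, sp)
  expect_true(all(diff(v) < 0))
  d0 <- 1500
  kappas <- c(1e-4, 5e-4, 1e-3, 5e-3)
  vk <- vapply(kappas, function(k) {
    matern_covariance(d0, matern_spec(k, tau_from_sigma_kappa(1, k)))
  }, numeric(1))
  expect_true(all(diff(vk) < 0))
})

test_that("range formula matches printed prior calibration and correlation drop", {
  expect_equal(range_from_kappa(0.00067, 0.5), 2985, tolerance = 1e-3)
  expect_equal(range_from_kappa(2, 0.5), 1)
  expect_equal(kappa_from_range(range_from_kappa(0.123)), 0.123, tolerance = 1e-12)
  # correlation at the range is exp(-2) ~ 0.135, i.e. close to 0.1
  sp <- matern_spec(0.00067, tau_from_sigma_kappa(1, 0.00067))
  corr_at_r <- matern_covariance(sp$range_bp, sp) / sp$sigma^2
  expect_equal(corr_at_r, exp(-2), tolerance = 1e-10)
  expect_error(range_from_kappa(0), "kappa")
  expect_error(kappa_from_range(-3), "range_bp")
})

test_that("default priors reproduce the printed prior means", {
  pr <- default_priors()
  expect_equal(exp(pr$logtau_mean), 27.39, tolerance = 2e-4)
  expect_equal(exp(pr$logkappa_mean), 0.00067, tolerance = 1e-2)
  # closed form: solve 1/(2 kappa tau^2) = 1 with kappa = 2/3000
  expect_equal(exp(pr$logtau_mean), sqrt(750), tolerance = 1e-12)
  expect_equal(pr$beta_mean, 0)
  expect_equal(pr$beta_variance, 1e6)
  expect_equal(pr$noise_shape, 1)
  expect_equal(pr$noise_rate, 5e-5)
  expect_equal(pr$logtau_precision, 0.05)
  expect_equal(pr$logkappa_precision, 0.05)
  # range0 = 2/kappa with kappa = 1 gives kappa_m = 1
  pr2 <- default_priors(range0 = 2)
  expect_equal(exp(pr2$logkappa_mean), 1, tolerance = 1e-12)
  expect_error(default_priors(range0 = -1), "range0")
})

test_that("markov precision inverts to the dense exponential covariance", {
  sp <- matern_spec(0.0008, 12)
  # single site: scalar precision 1/sigma^2
  mp1 <- markov_precision(1000, sp)
  expect_equal(mp1$diag, 1 / sp$sigma^2)
  # small irregular set against dense inversion
  pos <- c(100, 340, 400, 2100, 9000)
  mp <- markov_precision(pos, sp)
  Cd <- dense_ou_cov(pos, sp$sigma^2, sp$kappa)
  expect_lt(max(abs(solve(as.matrix(mp)) - Cd)), 1e-10)
  expect_equal(mp$logdet, -determinant(Cd)$modulus[[1]], tolerance = 1e-10)
  # equally spaced: constant off-diagonal band
  mpe <- markov_precision(seq(0, 9000, by = 1000), sp)
  expect_lt(diff(range(mpe$offdiag)), 1e-12)
  expect_lt(diff(range(mpe$diag[2:9])), 1e-12)
  expect_error(markov_precision(c(3, 1, 2), sp), "increasing")
  expect_error(markov_precision(c(1, 1, 2), sp), "increasing")
  sp15 <- matern_spec(0.001, 3, lambda = 1.5)
  expect_error(markov_precision(pos, sp15), "lambda = 0.5")
})

test_that("markov representation agrees with the covariance function on random layouts", {
  set.seed(11)
  for (rep in 1:3) {
    n <- sample(50:150, 1)
    pos <- sort(sample.int(5e5, n))
    kap <- exp(stats::runif(1, log(1e-4), log(1e-2)))
    sp <- matern_spec(kap, tau_from_sigma_kappa(exp(stats::runif(1, -1, 1)), kap))
    Cinv <- solve(as.matrix(markov_precision(pos, sp)))
    Cfun <- outer(pos, pos, function(a, b) matern_covariance(abs(a - b), sp))
    expect_lt(max(abs(Cinv - Cfun)), 1e-8)
  }
})
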