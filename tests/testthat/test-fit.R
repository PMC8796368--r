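test_that("O(n) marginal likelihood matches the dense Cholesky oracle", {
  pr <- default_priors()
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    pos <- sort(sample.int(3e5, n))
    y <- stats::rnorm(n, sd = stats::runif(1, 0.5, 2))
    tr <- chromosome_track(pos, y)
    th <- c(stats::runif(1, 2, 5), stats::runif(1, -9, -5), stats::runif(1, -1, 2))
    ours <- log_marginal_likelihood(tr, th, pr)
    oracle <- dense_loglik(pos, y, 1 / (2 * exp(th[2]) * exp(th[1])^2),
                           exp(th[2]), exp(-th[3]),
                           pr$beta_mean, pr$beta_variance)
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("marginal likelihood approaches the iid closed form when range << spacing", {
  pr <- default_priors()
  set.seed(4)
  n <- 200
  pos <- sort(sample(seq(1, 1e6, by = 50), n))
  y <- stats::rnorm(n)
  tr <- chromosome_track(pos, y)
  # kappa * minimal gap > 40: correlation numerically zero between all sites
  kap <- 45 / min(diff(pos))
  tau <- tau_from_sigma_kappa(0.8, kap)
  th <- c(log(tau), log(kap), log(1 / 0.3))
  ours <- log_marginal_likelihood(tr, th, pr)
  # iid limit: y ~ N(b0, (sigma^2 + sigma0^2) I + v0 J), Sherman-Morrison
  s <- 0.8^2 + 0.3
  v0 <- pr$beta_variance
  d <- y - pr$beta_mean
  logdet <- n * log(s) + log1p(n * v0 / s)
  quad <- sum(d^2) / s - v0 * sum(d)^2 / (s * (s + n * v0))
  iid <- -0.5 * (n * log(2 * pi) + logdet + quad)
  expect_equal(ours, iid, tolerance = 1e-4)
})

test_that("single-observation track has the closed-form univariate density", {
  pr <- default_priors()
  tr <- chromosome_track(1500, 0.7)
  th <- c(3, -7, 0.5)
  s2 <- 1 / (2 * exp(-7) * exp(3)^2)
  expect_equal(
    log_marginal_likelihood(tr, th, pr),
    stats::dnorm(0.7, pr$beta_mean, sqrt(s2 + exp(-0.5) + pr$beta_variance), log = TRUE)
  )
  expect_error(log_marginal_likelihood(tr, c(NA, 1, 1), pr), "finite")
})

test_that("with no data the posterior equals the prior", {
  pr <- default_priors()
  empty <- chromosome_track(numeric(0), numeric(0))
  f <- fit_chromosome(empty, pr)
  expect_equal(f$post_mean_logtau, log(27.39), tolerance = 0.02)
  expect_equal(f$post_mean_logkappa, log(0.00067), tolerance = 0.02)
  expect_equal(f$post_sd_logtau, 1 / sqrt(0.05), tolerance = 0.05 / sqrt(0.05))
})

test_that("fits are deterministic and posterior weights well formed", {
  tr <- sim_test_track(300, seed = 31)
  f1 <- fit_chromosome(tr)
  f2 <- fit_chromosome(tr)
  expect_identical(f1[setdiff(names(f1), "grid")], f2[setdiff(names(f2), "grid")])
  expect_true(is.finite(f1$log_evidence))
  expect_gt(f1$post_sd_logtau, 0)
  expect_gt(f1$post_sd_logkappa, 0)
})

test_that("posterior means cover truth at the simulation's stated settings", {
  pr <- default_priors()
  kap <- kappa_from_range(3000)
  tau <- tau_from_sigma_kappa(1, kap)
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    pos <- test_positions(2000, seed = 600 + r)
    y <- simulate_track(pos, matern_spec(kap, tau), 0.5, seed = 700 + r)$y
    f <- fit_chromosome(chromosome_track(pos, y), pr)
    ok_tau <- abs(f$post_mean_logtau - log(tau)) <= 3 * f$post_sd_logtau
    ok_kap <- abs(f$post_mean_logkappa - log(kap)) <= 3 * f$post_sd_logkappa
    hits <- hits + (ok_tau && ok_kap)
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("grid quadrature agrees with a long Metropolis run on the dense oracle", {
  pr <- default_priors()
  tr <- sim_test_track(120, seed = 77)
  f <- fit_chromosome(tr, pr)
  mh <- mh_posterior_means(tr$positions, tr$residuals, pr,
                           n_iter = 20000, burn = 5000, seed = 5)
  expect_gt(mh$accept, 0.1)
  expect_lt(abs(f$post_mean_logtau - mh$means[1]), 0.05)
  expect_lt(abs(f$post_mean_logkappa - mh$means[2]), 0.05)
})

test_that("plain fit recovers iid moments and ignores positions", {
  pr <- default_priors()
  # all-zero data: posterior mean intercept ~ 0
  tr0 <- chromosome_track(sort(sample.int(1e5, 200)), rep(0, 200))
  f0 <- fit_plain(tr0, pr)
  expect_lt(abs(f0$beta), 1e-6)
  # iid N(2, 1)
  set.seed(8)
  n <- 5000
  y <- stats::rnorm(n, 2, 1)
  tr <- chromosome_track(seq_len(n) * 10, y)
  f <- fit_plain(tr, pr)
  expect_equal(f$beta, 2, tolerance = 0.05)
  expect_equal(f$sigma0sq, 1, tolerance = 0.05)
  # shuffling positions leaves the fit unchanged (model is exchangeable)
  perm <- sample(n)
  tr_shuf <- chromosome_track(sort(sample.int(1e8, n)), y[perm])
  f_shuf <- fit_plain(tr_shuf, pr)
  expect_equal(f_shuf$beta, f$beta, tolerance = 1e-10)
  expect_equal(f_shuf$dic, f$dic, tolerance = 1e-8)
})

test_that("plain-model effective parameter count is about 2 on iid data", {
  pr <- default_priors()
  set.seed(13)
  y <- stats::rnorm(5000, 1, 1.3)
  f <- fit_plain(chromosome_track(seq_len(5000), y), pr)
  expect_equal(f$pd, 2, tolerance = 0.25)
  expect_identical(compute_dic(f)$dic, f$dic)
  # recomputation is bit-identical
  f2 <- fit_plain(chromosome_track(seq_len(5000), y), pr)
  expect_identical(f$dic, f2$dic)
})

test_that("model comparison favors the generating model", {
  pr <- default_priors()
  favored_dep <- favored_null <- 0L
  for (r in 1:8) {
    tr <- sim_test_track(400, seed = 900 + r)
    cmp <- compare_models(fit_chromosome(tr, pr), fit_plain(tr, pr))
    favored_dep <- favored_dep + (cmp$favored == "dependency")
    pos <- test_positions(400, seed = 950 + r)
    set.seed(960 + r)
    trn <- chromosome_track(pos, stats::rnorm(400))
    cmpn <- compare_models(fit_chromosome(trn, pr), fit_plain(trn, pr))
    favored_null <- favored_null + (cmpn$favored == "dependency")
  }
  expect_gte(favored_dep, 7L)
  expect_lte(favored_null, 1L)
})

test_that("model comparison validates inputs and handles the tie region", {
  pr <- default_priors()
  tr <- sim_test_track(120, seed = 41)
  dep <- fit_chromosome(tr, pr)
  pl <- fit_plain(tr, pr)
  dep_tied <- dep
  dep_tied$dic <- pl$dic
  expect_identical(compare_models(dep_tied, pl)$favored, "indeterminate")
  other <- fit_plain(sim_test_track(110, seed = 42), pr)
  expect_error(compare_models(dep, other), "same track")
})

test_that("variance explained is the noise-variance ratio complement", {
  pr <- default_priors()
  tr <- sim_test_track(150, seed = 55)
  dep <- fit_chromosome(tr, pr)
  pl <- fit_plain(tr, pr)
  dep_eq <- dep; dep_eq$sigma0sq <- pl$sigma0sq
  expect_equal(variance_explained(dep_eq, pl), 0)
  dep_q <- dep; dep_q$sigma0sq <- 0.25
  pl_1 <- pl; pl_1$sigma0sq <- 1
  expect_equal(variance_explained(dep_q, pl_1), 0.75)
  pl_0 <- pl; pl_0$sigma0sq <- 0
  expect_error(variance_explained(dep, pl_0), "zero")
})

test_that("variance explained grows with the spatial signal", {
  pr <- default_priors()
  ve <- sapply(c(0.5, 1.5), function(sig) {
    mean(sapply(1:6, function(r) {
      pos <- test_positions(400, seed = 1200 + r)
      kap <- kappa_from_range(3000)
      y <- simulate_track(pos, matern_spec(kap, tau_from_sigma_kappa(sig, kap)),
                          0.5, seed = 1300 + r)$y
      tr <- chromosome_track(pos, y)
      variance_explained(fit_chromosome(tr, pr), fit_plain(tr, pr))
    }))
  })
  expect_gt(ve[2], ve[1])
})

test_that("fit_cohort assembles the parameter table and tolerates isolated failures", {
  cfg <- cohort_sim_config(n_families = 3, n_chromosomes = 2,
                           sites_per_chromosome = 120, missing_rate = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  tracks <- preprocess_methylation(sim$matrix, sim$manifest, min_sites = 30)
  fits <- fit_cohort(tracks, config = grid_config(n_nodes = 7))
  expect_equal(nrow(fits), 12)   # 6 samples x 2 chromosomes
  expect_setequal(
    names(fits),
    c("sample_id", "chrom", "n_sites", "post_mean_logtau", "post_sd_logtau",
      "post_mean_logkappa", "post_sd_logkappa", "beta", "sigma0sq", "range_bp",
      "sigma", "dic_dep", "dic_plain", "delta_dic", "favored", "var_explained",
      "boundary_flag")
  )
  # determinism of the full table
  fits2 <- fit_cohort(tracks, config = grid_config(n_nodes = 7))
  expect_equal(fits, fits2)
})
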