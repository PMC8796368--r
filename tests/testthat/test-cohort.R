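test_that("ICC(1,1) matches a hand ANOVA and hits its boundary cases", {
  # 4 individuals x 3 replicates, worked by hand through the mean squares
  toy <- tibble::tibble(
    id = rep(c("a", "b", "c", "d"), each = 3),
    value = c(5.1, 5.3, 5.2, 7.0, 7.4, 7.2, 4.0, 3.8, 4.2, 6.1, 6.0, 6.2)
  )
  n <- 4; k <- 3
  gm <- mean(toy$value)
  mi <- tapply(toy$value, toy$id, mean)
  msb <- k * sum((mi - gm)^2) / (n - 1)
  msw <- sum((toy$value - mi[toy$id])^2) / (n * (k - 1))
  icc_hand <- (msb - msw) / (msb + (k - 1) * msw)
  res <- icc_oneway(toy, value, id)
  expect_equal(res$icc, icc_hand, tolerance = 1e-12)
  expect_lt(res$ci_low, res$icc)
  expect_gt(res$ci_high, res$icc)
  # identical replicates within individuals, distinct between: ICC = 1
  perfect <- tibble::tibble(id = rep(1:3, each = 2), value = rep(c(1, 5, 9), each = 2))
  expect_equal(icc_oneway(perfect, value, id)$icc, 1)
  # no between-individual component: ICC near 0 on average
  iccs <- sapply(1:6, function(s) {
    set.seed(s)
    d <- tibble::tibble(id = rep(1:30, each = 5), value = stats::rnorm(150))
    icc_oneway(d, value, id)$icc
  })
  expect_lt(abs(mean(iccs)), 0.1)
  expect_error(icc_oneway(perfect[1:2, ], value, id), "2 subjects")
})

test_that("pairing schemes satisfy their structural contracts", {
  # sheet sized like the study: 604 complete twin pairs
  cfg <- cohort_sim_config(n_families = 604, n_chromosomes = 1,
                           sites_per_chromosome = 10, seed = 31)
  sheet <- simulate_cohort(cfg)$sheet
  tw <- build_pairing(sheet, "true_twins")
  expect_equal(nrow(tw), 604)
  cot <- setNames(sheet$sample_id[seq(2, 1208, 2)], sheet$sample_id[seq(1, 1208, 2)])
  for (scheme in c("random", "matched_plate", "matched_plate_chip")) {
    pr <- build_pairing(sheet, scheme, seed = 7, n_repeats = 3)
    one <- pr[pr$rep == 1, ]
    expect_false(any(duplicated(c(one$a, one$b))))            # disjoint
    expect_false(any(one$a == one$b))
    # never a true co-twin pair
    pid <- setNames(sheet$pair_id, sheet$sample_id)
    expect_false(any(pid[one$a] == pid[one$b]))
    if (scheme != "random") {
      plate <- setNames(sheet$plate, sheet$sample_id)
      expect_true(all(plate[one$a] == plate[one$b]))
    }
    if (scheme == "matched_plate_chip") {
      chip <- setNames(sheet$beadchip, sheet$sample_id)
      expect_true(all(chip[one$a] == chip[one$b]))
    }
    # determinism in the seed
    expect_identical(build_pairing(sheet, scheme, seed = 7, n_repeats = 3), pr)
    expect_false(identical(build_pairing(sheet, scheme, seed = 8, n_repeats = 3)$a,
                           pr$a))
  }
})

test_that("squared pair differences are exact, symmetric and chromosome-aware", {
  tab <- tibble::tibble(
    sample_id = rep(c("x", "y"), each = 2), chrom = rep(1:2, 2),
    post_mean_logtau = c(1, 2, 3, 5), post_mean_logkappa = c(0, 0, 1, 4)
  )
  pairing <- tibble::tibble(rep = 1L, a = "x", b = "y")
  d <- pair_squared_diffs(tab, pairing)
  expect_equal(d$d_logtau, c(4, 9))
  expect_equal(d$d_logkappa, c(1, 16))
  # symmetry under member swap
  d2 <- pair_squared_diffs(tab, tibble::tibble(rep = 1L, a = "y", b = "x"))
  expect_equal(d2$d_logtau, d$d_logtau)
  # identical rows give zero
  tab0 <- tab; tab0[tab0$sample_id == "y", 3:4] <- tab0[tab0$sample_id == "x", 3:4]
  expect_true(all(pair_squared_diffs(tab0, pairing)$d_logtau == 0))
  # no shared chromosome: pair dropped with warning
  tab3 <- tab[c(1, 4), ]
  expect_warning(out <- pair_squared_diffs(tab3, pairing), "no shared chromosome")
  expect_equal(nrow(out), 0)
})

test_that("one-sided Mann-Whitney matches exact enumeration and the normal path", {
  r <- mann_whitney_one_sided(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$U, 9)
  expect_equal(r$p, 1 / choose(6, 3))   # only one assignment as extreme
  # against wilcox.test's exact p on untied small samples
  set.seed(5)
  x <- stats::rnorm(6, 1); y <- stats::rnorm(7)
  expect_equal(mann_whitney_one_sided(x, y)$p,
               stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large-sample path against wilcox.test's tie-corrected normal approximation
  set.seed(6)
  xl <- round(stats::rnorm(30, 0.3), 1); yl <- round(stats::rnorm(35), 1)
  expect_equal(mann_whitney_one_sided(xl, yl)$p,
               suppressWarnings(stats::wilcox.test(
                 xl, yl, alternative = "greater", exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-10)
  # direction sanity: stochastically smaller group gives p near 1
  expect_gt(mann_whitney_one_sided(stats::rnorm(40, -2), stats::rnorm(40, 2))$p, 0.99)
  # invariance under a common monotone transform
  expect_equal(mann_whitney_one_sided(exp(xl), exp(yl))$p,
               mann_whitney_one_sided(xl, yl)$p)
  # fully tied inputs do not fail
  expect_equal(mann_whitney_one_sided(rep(1, 30), rep(1, 30))$p, 1)
})

test_that("correlated p-value combination has the right limits", {
  p <- c(0.01, 0.04, 0.2, 0.5)
  k <- length(p)
  # zero correlation: exactly Fisher's method
  r0 <- combine_correlated_pvalues(p, rho = diag(k))
  fisher <- stats::pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
  expect_equal(r0$p_combined, fisher, tolerance = 1e-12)
  expect_equal(r0$df, 2 * k)
  # perfect correlation with equal p: combined ~ the single-test p
  pe <- rep(0.03, 5)
  r1 <- combine_correlated_pvalues(pe, rho = matrix(1, 5, 5))
  expect_equal(r1$p_combined, 0.03, tolerance = 1e-6)
  # moderate correlation: bracketed by Fisher and the max single p
  set.seed(12)
  z <- matrix(stats::rnorm(200), 50, 4) + stats::rnorm(50)
  r2 <- combine_correlated_pvalues(p, estimates = z)
  expect_gt(r2$p_combined, fisher)
  expect_lt(r2$p_combined, max(p))
  # zero p floored with warning; non-PSD matrix shrunk with warning
  expect_warning(combine_correlated_pvalues(c(0, 0.5), rho = diag(2)), "floored")
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_warning(combine_correlated_pvalues(c(0.1, 0.2, 0.3), rho = bad),
                 "positive semi-definite")
})

test_that("combined p-values are calibrated under a correlated null", {
  set.seed(99)
  k <- 6; n_per <- 25
  reps <- 2000
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    shared <- stats::rnorm(2 * n_per)
    z <- sqrt(0.5) * shared + sqrt(0.5) * matrix(stats::rnorm(2 * n_per * k), ncol = k)
    g1 <- z[1:n_per, , drop = FALSE]
    g2 <- z[(n_per + 1):(2 * n_per), , drop = FALSE]
    pk <- vapply(seq_len(k), function(j)
      mann_whitney_one_sided(g1[, j], g2[, j])$p, numeric(1))
    ps[r] <- combine_correlated_pvalues(pk, estimates = z)$p_combined
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("relative range is scale-free with median one per individual", {
  tab <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 5), chrom = rep(1:5, 2),
    range_bp = c(1000, 2000, 3000, 4000, 5000, 10, 20, 30, 40, 50)
  )
  per <- relative_range(tab, summarize = FALSE)
  expect_equal(per$rel_range[per$sample_id == "a"],
               per$rel_range[per$sample_id == "b"])   # scale invariance
  med_per_ind <- tapply(per$rel_range, per$sample_id, stats::median)
  expect_true(all(med_per_ind == 1))                  # odd chromosome count
  summ <- relative_range(tab)
  expect_equal(summ$rel_range_median, c(1, 2, 3, 4, 5) / 3)
  # constant ranges: all relative values one
  tab1 <- tibble::tibble(sample_id = "a", chrom = 1:4, range_bp = 2)
  expect_true(all(relative_range(tab1, summarize = FALSE)$rel_range == 1))
})

test_that("spearman correlation matches a rank-then-pearson oracle with sane CI", {
  set.seed(2)
  x <- stats::rnorm(22); y <- 0.3 * x + stats::rnorm(22)
  r <- spearman_with_ci(x, y)
  expect_equal(r$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_lt(r$ci_low, r$rho); expect_gt(r$ci_high, r$rho)
  expect_equal(spearman_with_ci(1:10, 10:1)$rho, -1)
  # invariance to monotone transforms
  expect_equal(spearman_with_ci(exp(x), y^3 - 2 * y)$rho,
               spearman_with_ci(x, y^3 - 2 * y)$rho)
  expect_error(spearman_with_ci(rep(1, 8), 1:8), "constant")
})

test_that("island proportions are relative to the chromosome median", {
  man <- tibble::tibble(
    chrom = rep(1:2, each = 10),
    island = c(rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 2),
               rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 2))
  )
  ip <- island_proportions(man)
  expect_equal(ip$prop_island, c(0.2, 0.4))
  expect_equal(ip$rel_prop, c(0.2, 0.4) / 0.3)
  # counting oracle on a simulated manifest
  cfg <- cohort_sim_config(n_families = 2, n_chromosomes = 3,
                           sites_per_chromosome = 300, seed = 4)
  sim <- simulate_cohort(cfg)
  ip2 <- island_proportions(sim$manifest)
  oracle <- tapply(sim$manifest$island, sim$manifest$chrom, mean)
  expect_equal(ip2$prop_island, as.numeric(oracle))
  # all-island manifest: relative proportions all one
  expect_true(all(island_proportions(
    tibble::tibble(chrom = rep(1:3, 5), island = TRUE))$rel_prop == 1))
})

test_that("age contrast detects a shift, is null-calibrated and directional", {
  make_table <- function(shift, seed) {
    set.seed(seed)
    n_young <- 60; n_old <- 30; k <- 6
    ids <- sprintf("S%03d", 1:(n_young + n_old))
    age <- c(round(stats::rnorm(n_young, 25, 3)), round(stats::rnorm(n_old, 62, 4)))
    base <- stats::rnorm(n_young + n_old, 0, 0.3) - shift * (age > 50)
    tibble::tibble(
      sample_id = rep(ids, each = k), chrom = rep(1:k, n_young + n_old),
      age = rep(age, each = k),
      post_mean_logtau = rep(base, each = k) + stats::rnorm(k * (n_young + n_old), 0, 0.1)
    )
  }
  shifted <- age_group_contrast(make_table(0.3, 1), params = "post_mean_logtau")
  expect_lt(shifted$combined$p_combined, 0.05)
  null <- age_group_contrast(make_table(0, 2), params = "post_mean_logtau")
  expect_gt(null$combined$p_combined, 0.01)
  # swapped direction lands in the complementary region
  up <- age_group_contrast(make_table(0.3, 1), params = "post_mean_logtau",
                           direction = "old_greater")
  expect_gt(up$combined$p_combined, 0.5)
  pc <- age_group_contrast(make_table(0, 3), params = "post_mean_logtau")$per_chromosome
  swapped <- age_group_contrast(make_table(0, 3), params = "post_mean_logtau",
                                direction = "old_greater")$per_chromosome
  expect_lt(max(abs(pc$p + swapped$p - 1)), 0.02)
})

test_that("pairing scheme medians recover the simulated similarity ordering", {
  # uses the generator's true parameters as the table, isolating the
  # pairing statistics from estimation noise
  ok <- 0L
  for (s in 1:5) {
    cfg <- cohort_sim_config(n_families = 150, n_chromosomes = 4,
                             sites_per_chromosome = 10, seed = 400 + s)
    sim <- simulate_cohort(cfg)
    tab <- dplyr::rename(sim$truth[c("sample_id", "chrom", "logtau", "logkappa")],
                         post_mean_logtau = "logtau", post_mean_logkappa = "logkappa")
    pt <- pairing_tests(tab, sim$sheet, seed = s, n_repeats = 20)
    md <- attr(pt, "scheme_median_d")
    md <- md[md$param == "logtau", ]
    v <- setNames(md$median_d, md$scheme)
    ok <- ok + (v["true_twins"] < v["matched_plate_chip"] &&
                  v["matched_plate_chip"] < v["matched_plate"] &&
                  v["matched_plate"] < v["random"])
  }
  expect_gte(ok, 4L)
})

test_that("the representative pairing is the middle rank by median D", {
  set.seed(9)
  tab <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:20), chrom = 1,
    post_mean_logtau = stats::rnorm(20), post_mean_logkappa = stats::rnorm(20)
  )
  pairing <- dplyr::bind_rows(lapply(1:9, function(r) {
    ids <- sample(tab$sample_id)
    tibble::tibble(rep = r, a = ids[1:10], b = ids[11:20])
  }))
  d <- pair_squared_diffs(tab, pairing)
  rep_d <- representative_pairing(d, "d_logtau")
  meds <- sort(tapply(d$d_logtau, d$rep, stats::median))
  expect_equal(stats::median(rep_d$d_logtau), as.numeric(meds[5]))
})
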