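derive_seed <- function(seed, k) {
  x <- as.double(seed) %% 2147483647
  x <- (x * 48271 + as.double(k) %% 2147483647) %% 2147483647
  as.integer(x) + 1L
}

#' Configuration of the synthetic twin-cohort simulator
#'
#' Defines every knob of the forward model used to generate synthetic
#' methylation cohorts with known ground truth: cohort composition, CpG
#' position geometry, the latent-field parameter hierarchy (individual
#' level, cross-chromosome spread, twin correlation by zygosity), batch
#' structure (plate and BeadChip shifts, one outlier plate), demographic
#' effects (age-group shift on log tau, a sex offset), measurement noise
#' and missingness.
#'
#' The defaults describe the cohort the package's validation suite runs
#' on: 200 twin pairs (55% MZ), two age groups (about a quarter older,
#' ages ~N(62,5) vs ~N(23,3)), co-twins always on the same conversion
#' plate and mostly on the same BeadChip, latent field with range 3000 bp
#' and marginal variance 0.75 against noise sd 0.5 (total residual
#' variance ~1, matching the population normalization).
#'
#' @param n_families Number of twin pairs.
#' @param mz_fraction Fraction of pairs that are monozygotic.
#' @param n_chromosomes Number of simulated autosomes (<= 22).
#' @param sites_per_chromosome CpG sites per chromosome.
#' @param island_width_bp,island_spacing_bp,background_spacing_bp CpG
#'   position geometry: island extent, within-island mean gap, and
#'   background mean gap.
#' @param island_prop_range Range of per-chromosome island proportions
#'   (drawn uniformly).
#' @param field_range_bp,field_sigma2 Population-level dependency: range
#'   (bp) and marginal variance of the latent field; the log kappa / log
#'   tau population means derive from these.
#' @param ind_sd Between-individual sd of log tau and log kappa.
#' @param chrom_sd Within-individual, between-chromosome sd.
#' @param mz_cor,dz_cor Twin correlation of the individual-level
#'   parameters for MZ and DZ pairs.
#' @param plate_sd,chip_sd Batch-effect sds on log tau and log kappa.
#' @param plate_intercept_sd Plate shift sd on the track intercept.
#' @param outlier_plate_shift Extra shift c(log tau, log kappa, intercept)
#'   applied to one plate (emulating a deviant processing batch).
#' @param age_shift_logtau Additive shift of log tau for the older group
#'   (negative: more field variance with age).
#' @param age_old_fraction Fraction of families in the older group.
#' @param dz_opposite_frac Fraction of DZ pairs that are opposite-sex.
#' @param sex_effect Offset added to log tau (and subtracted from
#'   log kappa) for males.
#' @param sigma0 Measurement noise sd on the residual (M) scale.
#' @param missing_rate Independent missingness probability per value.
#' @param pairs_per_plate,pairs_per_chip Plate and BeadChip capacities.
#' @param chip_share Probability that a pair shares a BeadChip.
#' @param seed Master seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_families = 200, mz_fraction = 0.556,
                              n_chromosomes = 6, sites_per_chromosome = 400,
                              island_width_bp = 1000, island_spacing_bp = 60,
                              background_spacing_bp = 2500,
                              island_prop_range = c(0.25, 0.45),
                              field_range_bp = 3000, field_sigma2 = 0.75,
                              ind_sd = 0.35, chrom_sd = 0.12,
                              mz_cor = 0.9, dz_cor = 0.5,
                              plate_sd = 0.3, chip_sd = 0.18,
                              plate_intercept_sd = 0.1,
                              outlier_plate_shift = c(-0.5, 0.4, 0.3),
                              age_shift_logtau = -0.3, age_old_fraction = 0.26,
                              dz_opposite_frac = 0.35, sex_effect = 0.12,
                              sigma0 = 0.5, missing_rate = 0.01,
                              pairs_per_plate = 26, pairs_per_chip = 6,
                              chip_share = 0.8, seed = 1L) {
  cfg <- as.list(environment())
  problems <- character(0)
  if (n_families < 2) problems <- c(problems, "n_families must be >= 2")
  if (mz_fraction < 0 || mz_fraction > 1) problems <- c(problems, "mz_fraction must be in [0,1]")
  if (n_chromosomes < 1 || n_chromosomes > 22) problems <- c(problems, "n_chromosomes must be in 1..22")
  if (sites_per_chromosome < 10) problems <- c(problems, "sites_per_chromosome must be >= 10")
  if (any(c(ind_sd, chrom_sd, plate_sd, chip_sd, plate_intercept_sd, sigma0) < 0)) {
    problems <- c(problems, "all sds must be >= 0")
  }
  if (any(c(mz_cor, dz_cor) < -1 | c(mz_cor, dz_cor) > 1)) {
    problems <- c(problems, "twin correlations must be in [-1,1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) problems <- c(problems, "missing_rate must be in [0,1)")
  if (field_range_bp <= 0 || field_sigma2 <= 0) {
    problems <- c(problems, "field_range_bp and field_sigma2 must be > 0")
  }
  if (length(problems)) stop("invalid simulator config:\n  ", paste(problems, collapse = "\n  "))
  cfg$logkappa_mean <- log(kappa_from_range(field_range_bp))
  cfg$logtau_mean <- log(tau_from_sigma_kappa(sqrt(field_sigma2), exp(cfg$logkappa_mean)))
  structure(cfg, class = "cohort_sim_config")
}

#' Simulate clustered CpG positions for one chromosome
#'
#' Lays out sites as a mixture of dense CpG islands (short mean gaps over
#' a limited width) and sparse background sites (long exponential gaps),
#' emulating the clustered spacing of array CpGs. The island proportion is
#' drawn from the configured range per chromosome.
#'
#' @param config A [cohort_sim_config()].
#' @param chrom Chromosome index (used only to vary island proportion).
#' @param seed Seed for this chromosome's geometry.
#' @return A tibble with sorted integer `pos` and logical `island`.
#' @export
simulate_positions <- function(config, chrom = 1L, seed = config$seed) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(seed)
  n <- config$sites_per_chromosome
  prop <- stats::runif(1, config$island_prop_range[1], config$island_prop_range[2])
  n_isl_sites <- round(prop * n)
  sites_per_island <- max(2L, round(config$island_width_bp / config$island_spacing_bp))
  n_islands <- max(if (n_isl_sites > 0) 1L else 0L,
                   round(n_isl_sites / sites_per_island))
  n_bg <- n - n_isl_sites
  # island blocks are inserted after randomly chosen background sites
  insert_after <- sort(sample.int(max(n_bg - 1, 1), n_islands, replace = FALSE))
  isl_sizes <- rep(n_isl_sites %/% max(n_islands, 1), length.out = n_islands)
  if (n_islands > 0 && sum(isl_sizes) < n_isl_sites) {
    isl_sizes[seq_len(n_isl_sites - sum(isl_sizes))] <-
      isl_sizes[seq_len(n_isl_sites - sum(isl_sizes))] + 1L
  }
  gaps <- numeric(0); flags <- logical(0)
  k <- 0L
  for (b in seq_len(n_bg)) {
    gaps <- c(gaps, stats::rexp(1, 1 / config$background_spacing_bp) + 100)
    flags <- c(flags, FALSE)
    hit <- which(insert_after == b)
    for (h in hit) {
      k <- k + 1L
      m <- isl_sizes[k]
      gaps <- c(gaps, stats::rexp(m, 1 / config$island_spacing_bp) + 10)
      flags <- c(flags, rep(TRUE, m))
    }
  }
  if (n_bg == 0) {
    gaps <- stats::rexp(n, 1 / config$island_spacing_bp) + 10
    flags <- rep(TRUE, n)
  }
  pos <- floor(1e5 + cumsum(gaps))
  pos <- cummax(pos + seq_along(pos) * 0)          # already increasing
  if (any(diff(pos) <= 0)) pos <- pos + seq_along(pos)  # guard integer ties
  tibble::tibble(pos = as.double(pos[seq_len(n)]), island = flags[seq_len(n)])
}

#' Simulate one residual track from the dependency model
#'
#' Draws the latent exponential-covariance field exactly through its
#' Markov property (sequential conditional Gaussians with lag correlation
#' \eqn{e^{-\kappa \Delta}}) and adds iid measurement noise.
#'
#' @param positions Sorted base-pair positions.
#' @param spec A [matern_spec()] with `lambda = 0.5`.
#' @param sigma0 Noise sd.
#' @param seed Seed.
#' @param beta Track intercept (default 0).
#' @return A tibble with `pos`, `xi` (latent field) and `y`
#'   (observed residual).
#' @export
simulate_track <- function(positions, spec, sigma0, seed, beta = 0) {
  stopifnot(inherits(spec, "matern_spec"))
  if (spec$lambda != 0.5) stop("exact Markov simulation requires lambda = 0.5")
  if (length(positions) > 1 && is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  set.seed(seed)
  n <- length(positions)
  s <- spec$sigma
  xi <- numeric(n)
  z <- stats::rnorm(n)
  xi[1] <- s * z[1]
  if (n > 1) {
    rho <- exp(-spec$kappa * diff(positions))
    sd_c <- s * sqrt(1 - rho^2)
    for (i in 2:n) xi[i] <- rho[i - 1] * xi[i - 1] + sd_c[i - 1] * z[i]
  }
  y <- beta + xi + stats::rnorm(n, 0, sigma0)
  tibble::tibble(pos = as.double(positions), xi = xi, y = y)
}

#' Simulate a full synthetic twin cohort
#'
#' Generates a beta-scale methylation matrix, probe manifest, sample sheet
#' and ground-truth parameter table under the dependency model: per-pair
#' zygosity, sex, age group, plate and BeadChip assignment; individual
#' (log tau, log kappa) drawn with twin correlation by zygosity plus plate,
#' chip, age and sex effects; per-chromosome parameters around the
#' individual level; exact latent-field tracks plus noise; population
#' means drawn from a bimodal beta-scale distribution; residuals added on
#' the M scale and transformed back to beta values; independent
#' missingness.
#'
#' @param config A [cohort_sim_config()].
#' @return A list with elements `matrix` (beta-scale [meth_matrix()]),
#'   `manifest`, `sheet`, `truth` (per sample x chromosome true
#'   parameters) and `config`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  nf <- config$n_families
  nc <- config$n_chromosomes

  geo <- lapply(seq_len(nc), function(ch) {
    simulate_positions(config, ch, seed = derive_seed(config$seed, 1000 + ch))
  })
  manifest <- dplyr::bind_rows(lapply(seq_len(nc), function(ch) {
    tibble::tibble(chrom = ch, pos = geo[[ch]]$pos, island = geo[[ch]]$island)
  }))
  manifest <- tibble::tibble(
    probe_id = sprintf("cg%07d", seq_len(nrow(manifest))),
    chrom = manifest$chrom, pos = manifest$pos, island = manifest$island
  )

  set.seed(derive_seed(config$seed, 2))
  zyg <- ifelse(stats::runif(nf) < config$mz_fraction, "MZ", "DZ")
  old <- stats::runif(nf) < config$age_old_fraction
  age <- ifelse(old, pmin(pmax(round(stats::rnorm(nf, 62, 5)), 51), 80),
                pmin(pmax(round(stats::rnorm(nf, 23, 3)), 18), 39))
  sex1 <- ifelse(stats::runif(nf) < 0.5, "F", "M")
  sex2 <- ifelse(zyg == "MZ", sex1,
                 ifelse(stats::runif(nf) < config$dz_opposite_frac,
                        ifelse(sex1 == "F", "M", "F"), sex1))

  pair_order <- sample.int(nf)
  plate_of_pair <- integer(nf)
  plate_of_pair[pair_order] <- ceiling(seq_len(nf) / config$pairs_per_plate)
  n_plates <- max(plate_of_pair)
  chip_slot <- integer(nf)
  chip_slot[pair_order] <- ceiling(
    ((seq_len(nf) - 1) %% config$pairs_per_plate + 1) / config$pairs_per_chip
  )
  split_chip <- stats::runif(nf) > config$chip_share

  outlier_plate <- sample.int(n_plates, 1)
  plate_eff <- cbind(
    logtau = stats::rnorm(n_plates, 0, config$plate_sd),
    logkappa = stats::rnorm(n_plates, 0, config$plate_sd),
    intercept = stats::rnorm(n_plates, 0, config$plate_intercept_sd)
  )
  plate_eff[outlier_plate, ] <- plate_eff[outlier_plate, ] + config$outlier_plate_shift

  chip_key <- unique(data.frame(plate = plate_of_pair, slot = chip_slot))
  chip_key$extra_slot <- max(chip_key$slot) + 1
  n_chip_units <- nrow(chip_key) * 2   # room for the split co-twins
  chip_eff_tau <- stats::rnorm(n_chip_units, 0, config$chip_sd)
  chip_eff_kap <- stats::rnorm(n_chip_units, 0, config$chip_sd)

  chip_index <- function(plate, slot) {
    match(paste(plate, slot), paste(chip_key$plate, chip_key$slot))
  }

  n_samples <- 2L * nf
  sheet_rows <- vector("list", nf)
  ind <- tibble::tibble(
    sample_id = character(n_samples), logtau = numeric(n_samples),
    logkappa = numeric(n_samples), intercept = numeric(n_samples)
  )
  for (f in seq_len(nf)) {
    rho_z <- if (zyg[f] == "MZ") config$mz_cor else config$dz_cor
    shared <- stats::rnorm(2)   # (logtau, logkappa)
    for (j in 1:2) {
      i <- 2L * (f - 1L) + j
      uniq <- stats::rnorm(2)
      z <- sqrt(rho_z) * shared + sqrt(1 - rho_z) * uniq
      sx <- if (j == 1) sex1[f] else sex2[f]
      pl <- plate_of_pair[f]
      slot <- if (j == 2 && split_chip[f]) chip_slot[f] + 0.5 else chip_slot[f]
      ci <- if (slot %% 1 == 0) chip_index(pl, slot) else nrow(chip_key) + chip_index(pl, floor(slot))
      ind$sample_id[i] <- sprintf("S%04d", i)
      ind$logtau[i] <- config$logtau_mean + config$ind_sd * z[1] +
        plate_eff[pl, "logtau"] + chip_eff_tau[ci] +
        config$age_shift_logtau * old[f] +
        config$sex_effect * (sx == "M")
      ind$logkappa[i] <- config$logkappa_mean + config$ind_sd * z[2] +
        plate_eff[pl, "logkappa"] + chip_eff_kap[ci] -
        config$sex_effect * (sx == "M")
      ind$intercept[i] <- plate_eff[pl, "intercept"] + stats::rnorm(1, 0, 0.05)
      sheet_rows[[f]] <- dplyr::bind_rows(sheet_rows[[f]], tibble::tibble(
        sample_id = ind$sample_id[i], family_id = sprintf("F%04d", f),
        pair_id = sprintf("P%04d", f), zygosity = zyg[f], sex = sx,
        age = age[f], plate = sprintf("PL%02d", pl),
        beadchip = sprintf("CH%02d_%s", pl, format(slot))
      ))
    }
  }
  sheet <- dplyr::bind_rows(sheet_rows)

  # per-chromosome parameters and tracks
  truth <- vector("list", n_samples * nc)
  vals <- matrix(NA_real_, nrow(manifest), n_samples,
                 dimnames = list(manifest$probe_id, ind$sample_id))
  chrom_offsets <- c(0L, cumsum(vapply(geo, nrow, integer(1))))
  set.seed(derive_seed(config$seed, 3))
  chrom_dev_tau <- matrix(stats::rnorm(n_samples * nc, 0, config$chrom_sd), n_samples, nc)
  chrom_dev_kap <- matrix(stats::rnorm(n_samples * nc, 0, config$chrom_sd), n_samples, nc)
  for (i in seq_len(n_samples)) {
    for (ch in seq_len(nc)) {
      lt <- ind$logtau[i] + chrom_dev_tau[i, ch]
      lk <- ind$logkappa[i] + chrom_dev_kap[i, ch]
      sp <- matern_spec(kappa = exp(lk), tau = exp(lt))
      tr <- simulate_track(geo[[ch]]$pos, sp, config$sigma0,
                           seed = derive_seed(config$seed, 10000 + i * 100 + ch),
                           beta = ind$intercept[i])
      rows <- (chrom_offsets[ch] + 1):chrom_offsets[ch + 1]
      vals[rows, i] <- tr$y
      truth[[(i - 1) * nc + ch]] <- tibble::tibble(
        sample_id = ind$sample_id[i], chrom = ch,
        logtau = lt, logkappa = lk,
        sigma = sigma_from_tau_kappa(exp(lt), exp(lk)),
        range_bp = range_from_kappa(exp(lk)),
        intercept = ind$intercept[i]
      )
    }
  }
  truth <- dplyr::bind_rows(truth)

  # residuals -> M scale -> beta scale
  set.seed(derive_seed(config$seed, 4))
  p <- nrow(manifest)
  hi <- stats::runif(p) < 0.55
  mu_beta <- ifelse(hi, stats::rbeta(p, 8, 2), stats::rbeta(p, 2, 8))
  mu_beta <- pmin(pmax(mu_beta, 0.02), 0.98)
  s_p <- stats::runif(p, 0.15, 0.45)
  m_vals <- log2(mu_beta / (1 - mu_beta)) + s_p * vals
  beta_vals <- 2^m_vals / (1 + 2^m_vals)
  eps <- 1e-6
  beta_vals <- pmin(pmax(beta_vals, eps), 1 - eps)
  if (config$missing_rate > 0) {
    beta_vals[stats::runif(length(beta_vals)) < config$missing_rate] <- NA_real_
  }
  dim(beta_vals) <- dim(vals)
  dimnames(beta_vals) <- dimnames(vals)

  list(
    matrix = meth_matrix(beta_vals, scale = "beta"),
    manifest = manifest, sheet = sheet,
    truth = dplyr::left_join(truth, sheet, by = "sample_id"),
    config = config
  )
}
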