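#' One-way intraclass correlation, single measurement, absolute agreement
#'
#' ICC(1,1) treats each individual's per-chromosome posterior-mean
#' estimates as replicates and measures the fraction of total variance
#' attributable to between-individual differences:
#' \eqn{(MS_B - MS_W) / (MS_B + (k - 1) MS_W)}, with the unbalanced-design
#' replicate count \eqn{k_0 = (N - \sum n_i^2 / N)/(n - 1)} when group
#' sizes differ. The 95% confidence interval follows from the F
#' distribution of \eqn{MS_B / MS_W}.
#'
#' @param data A data frame with one row per (subject, replicate).
#' @param value Column holding the measured value (tidy-eval).
#' @param subject Column identifying the subject (tidy-eval).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `icc`, `ci_low`, `ci_high`, `n_subjects`, `k`.
#' @export
icc_oneway <- function(data, value, subject, conf_level = 0.95) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ subject }}))
  keep <- is.finite(v)
  v <- v[keep]; g <- droplevels(g[keep])
  n_i <- tabulate(g)
  if (nlevels(g) < 2) stop("ICC requires at least 2 subjects")
  if (any(n_i < 2)) stop("every subject needs at least 2 replicates")
  n <- nlevels(g); N <- length(v)
  gm <- mean(v)
  m_i <- tapply(v, g, mean)
  ssb <- sum(n_i * (m_i - gm)^2)
  ssw <- sum((v - m_i[g])^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(n_i^2) / N) / (n - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  fobs <- msb / msw
  alpha <- 1 - conf_level
  fl <- fobs / stats::qf(1 - alpha / 2, n - 1, N - n)
  fu <- fobs * stats::qf(1 - alpha / 2, N - n, n - 1)
  list(
    icc = icc,
    ci_low = (fl - 1) / (fl + k0 - 1),
    ci_high = (fu - 1) / (fu + k0 - 1),
    n_subjects = n, k = k0
  )
}

#' Select one individual per family
#'
#' Cohort-level ICCs are computed on one randomly chosen individual per
#' family so that twin resemblance does not inflate the between-individual
#' variance component.
#'
#' @param sheet A sample sheet tibble.
#' @param seed Selection seed (recorded in the result's
#'   `"selection_seed"` attribute).
#' @return Character vector of selected sample ids.
#' @export
one_per_family <- function(sheet, seed = 1L) {
  set.seed(seed)
  sel <- sheet |>
    dplyr::group_by(.data$family_id) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup() |>
    dplyr::pull("sample_id")
  attr(sel, "selection_seed") <- seed
  sel
}

pair_ids_within <- function(ids, cotwin, max_tries = 50) {
  # random disjoint pairing of ids avoiding true co-twin pairs
  m <- length(ids)
  if (m < 2) return(NULL)
  for (t in seq_len(max_tries)) {
    perm <- sample(ids)
    a <- perm[seq(1, m - m %% 2, by = 2)]
    b <- perm[seq(2, m - m %% 2, by = 2)]
    if (!any(cotwin[a] == b, na.rm = TRUE)) {
      return(tibble::tibble(a = a, b = b))
    }
  }
  # keep the last draw, dropping offending pairs
  bad <- cotwin[a] == b
  tibble::tibble(a = a[!bad], b = b[!bad])
}

#' Build a pairing of cohort individuals
#'
#' Four schemes mirror the pairing contrasts used to separate genetic from
#' batch structure: `true_twins` pairs each individual with their co-twin
#' (deterministic, one repeat); `random` pairs individuals arbitrarily;
#' `matched_plate` pairs within conversion plate; `matched_plate_chip`
#' within plate and BeadChip. Random schemes never pair true co-twins and
#' are repeated `n_repeats` times so that a representative repeat can be
#' chosen downstream by [representative_pairing()]. Odd strata leave one
#' sample unpaired.
#'
#' @param sheet A sample sheet tibble.
#' @param scheme One of `"true_twins"`, `"random"`, `"matched_plate"`,
#'   `"matched_plate_chip"`.
#' @param seed RNG seed (same seed, same pairings).
#' @param n_repeats Number of random repeats (default 100; ignored for
#'   `true_twins`).
#' @return A tibble with columns `rep`, `a`, `b`; attributes `scheme` and
#'   `seed`.
#' @export
build_pairing <- function(sheet, scheme = c("true_twins", "random",
                                            "matched_plate", "matched_plate_chip"),
                          seed = 1L, n_repeats = 100) {
  scheme <- match.arg(scheme)
  cotwin <- with(sheet, {
    x <- stats::setNames(rep(NA_character_, nrow(sheet)), sample_id)
    for (p in unique(pair_id)) {
      ids <- sample_id[pair_id == p]
      if (length(ids) == 2) { x[ids[1]] <- ids[2]; x[ids[2]] <- ids[1] }
    }
    x
  })
  if (scheme == "true_twins") {
    pairs <- sheet |>
      dplyr::group_by(.data$pair_id) |>
      dplyr::filter(dplyr::n() == 2) |>
      dplyr::summarise(a = .data$sample_id[1], b = .data$sample_id[2],
                       .groups = "drop") |>
      dplyr::select("a", "b")
    out <- dplyr::bind_cols(rep = 1L, pairs)
  } else {
    strata <- switch(scheme,
      random = list(sheet$sample_id),
      matched_plate = split(sheet$sample_id, sheet$plate),
      matched_plate_chip = split(sheet$sample_id,
                                 paste(sheet$plate, sheet$beadchip))
    )
    small <- vapply(strata, length, integer(1)) < 2
    if (all(small)) stop("fewer than 2 usable samples in every stratum")
    set.seed(seed)
    out <- dplyr::bind_rows(lapply(seq_len(n_repeats), function(r) {
      prs <- dplyr::bind_rows(lapply(strata[!small], pair_ids_within, cotwin = cotwin))
      dplyr::bind_cols(rep = as.integer(r), prs)
    }))
  }
  attr(out, "scheme") <- scheme
  attr(out, "seed") <- seed
  out
}

#' Squared pairwise differences of the dependency parameters
#'
#' For every pair and chromosome computes
#' \eqn{D_{\tau} = (\log\tau_A - \log\tau_B)^2} and likewise
#' \eqn{D_{\kappa}}; chromosomes missing for either pair member are
#' skipped, and pairs with no shared chromosome are dropped with a
#' warning.
#'
#' @param table A parameter table with columns `sample_id`, `chrom`,
#'   `post_mean_logtau`, `post_mean_logkappa` (e.g. from [fit_cohort()]).
#' @param pairing A pairing tibble from [build_pairing()].
#' @return A tibble with `rep`, `a`, `b`, `chrom`, `d_logtau`,
#'   `d_logkappa`.
#' @export
pair_squared_diffs <- function(table, pairing) {
  stopifnot(all(c("sample_id", "chrom", "post_mean_logtau", "post_mean_logkappa")
                %in% names(table)))
  tab <- table[c("sample_id", "chrom", "post_mean_logtau", "post_mean_logkappa")]
  out <- pairing |>
    dplyr::inner_join(tab, by = c(a = "sample_id"), relationship = "many-to-many") |>
    dplyr::inner_join(tab, by = c(b = "sample_id", chrom = "chrom"),
                      suffix = c("_a", "_b")) |>
    dplyr::mutate(
      d_logtau = (.data$post_mean_logtau_a - .data$post_mean_logtau_b)^2,
      d_logkappa = (.data$post_mean_logkappa_a - .data$post_mean_logkappa_b)^2
    ) |>
    dplyr::select("rep", "a", "b", "chrom", "d_logtau", "d_logkappa")
  n_dropped <- nrow(dplyr::anti_join(pairing, out, by = c("rep", "a", "b")))
  if (n_dropped > 0) {
    warning(sprintf("%d pair(s) had no shared chromosome and were dropped", n_dropped))
  }
  out
}

#' Representative repeat of a random pairing
#'
#' Ranks the repeats of a random pairing by the median of the chosen D
#' statistic and returns the repeat of middle rank
#' (\eqn{\lceil n/2 \rceil}), the operational reading of "the median
#' distribution, ranked by median".
#'
#' @param diffs Output of [pair_squared_diffs()] over all repeats.
#' @param param `"d_logtau"` or `"d_logkappa"`.
#' @return The rows of `diffs` belonging to the representative repeat.
#' @export
representative_pairing <- function(diffs, param = c("d_logtau", "d_logkappa")) {
  param <- match.arg(param)
  med <- diffs |>
    dplyr::group_by(.data$rep) |>
    dplyr::summarise(m = stats::median(.data[[param]]), .groups = "drop") |>
    dplyr::arrange(.data$m)
  pick <- med$rep[ceiling(nrow(med) / 2)]
  diffs[diffs$rep == pick, ]
}

#' One-sided Mann-Whitney test
#'
#' Tests the alternative that `greater` is stochastically larger than
#' `lesser`, using midranks for ties. For m + n <= 20 the p-value is
#' computed by exact enumeration over all group assignments of the
#' observed midranks; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param greater,lesser Numeric vectors (non-empty).
#' @return A list with the Mann-Whitney `U` of `greater` and one-sided `p`.
#' @export
mann_whitney_one_sided <- function(greater, lesser) {
  greater <- greater[is.finite(greater)]
  lesser <- lesser[is.finite(lesser)]
  m <- length(greater); n <- length(lesser)
  if (m == 0 || n == 0) stop("both groups must be non-empty")
  r <- rank(c(greater, lesser))            # midranks
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= 20) {
    combs <- utils::combn(m + n, m)
    Us <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p <- mean(Us >= U)
  } else {
    N <- m + n
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sd_u <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    if (sd_u == 0) return(list(U = U, p = 1))
    z <- (U - m * n / 2 - 0.5) / sd_u
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(U = U, p = max(p, .Machine$double.xmin))
}

kost_mcdermott <- function(rho) 3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3

#' Combine correlated per-chromosome p-values
#'
#' Extended Fisher's method for dependent tests: the statistic
#' \eqn{X = -2 \sum \ln p_j} has mean \eqn{2k} and, under dependence,
#' variance \eqn{4k + 2\sum_{i<j} cov_{ij}} with
#' \eqn{cov_{ij} = 3.263\rho_{ij} + 0.710\rho_{ij}^2 + 0.027\rho_{ij}^3}
#' (the Kost-McDermott polynomial approximation). \eqn{\rho_{ij}} is the
#' Pearson correlation between chromosomes i and j of the per-unit
#' statistic supplied in `estimates`. The combined p-value is the upper
#' tail of the moment-matched scaled chi-square \eqn{c\,\chi^2_f} with
#' \eqn{c = Var/(2E)}, \eqn{f = 2E^2/Var}. With all correlations zero the
#' procedure reduces exactly to Fisher's method.
#'
#' @param p Vector of per-chromosome p-values in (0, 1].
#' @param estimates Optional units-by-chromosomes matrix (or data frame)
#'   of the statistic underlying each test, used to estimate the
#'   between-chromosome correlation; `NULL` assumes independence.
#' @param rho Optional correlation matrix overriding `estimates`.
#' @param p_floor Values of exactly 0 are floored here with a warning.
#' @return A list of class `combined_test` with `p_by_chrom`, `rho`,
#'   `statistic` (X), `scale` (c), `df` (f) and `p_combined`.
#' @export
combine_correlated_pvalues <- function(p, estimates = NULL, rho = NULL,
                                       p_floor = 1e-300) {
  k <- length(p)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value(s) of 0 floored at p_floor")
    p[p == 0] <- p_floor
  }
  if (is.null(rho)) {
    if (is.null(estimates)) {
      rho <- diag(k)
    } else {
      estimates <- as.matrix(estimates)
      if (ncol(estimates) != k) stop("`estimates` must have one column per p-value")
      rho <- suppressWarnings(stats::cor(estimates, use = "pairwise.complete.obs"))
      rho[!is.finite(rho)] <- 0
      diag(rho) <- 1
    }
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("correlation matrix not positive semi-definite; shrinking toward identity")
    lam <- min(ev)
    w <- -lam / (1 - lam)
    rho <- (1 - w) * rho + w * diag(k)
  }
  X <- -2 * sum(log(p))
  EX <- 2 * k
  covs <- kost_mcdermott(rho[upper.tri(rho)])
  VX <- 4 * k + 2 * sum(covs)
  cc <- VX / (2 * EX)
  f <- 2 * EX^2 / VX
  structure(
    list(p_by_chrom = p, rho = rho, statistic = X, scale = cc, df = f,
         p_combined = stats::pchisq(X / cc, df = f, lower.tail = FALSE)),
    class = "combined_test"
  )
}

#' @export
print.combined_test <- function(x, ...) {
  cat(sprintf("Combined test over %d chromosomes: X = %.2f, scale = %.3f, df = %.2f, p = %.3g\n",
              length(x$p_by_chrom), x$statistic, x$scale, x$df, x$p_combined))
  invisible(x)
}

#' Relative range per chromosome
#'
#' Each individual's posterior-mean range estimates are divided by that
#' individual's median range across chromosomes, removing the large
#' between-individual level differences; the per-chromosome median of
#' these relative values across individuals profiles which chromosomes
#' carry systematically longer- or shorter-ranged dependence.
#'
#' @param table A parameter table with `sample_id`, `chrom`, `range_bp`.
#' @param summarize If `TRUE` (default) return the per-chromosome medians;
#'   otherwise the per-(sample, chromosome) relative values.
#' @return A tibble: `chrom`, `rel_range_median`, `n` (or sample-level
#'   rows with `rel_range`).
#' @export
relative_range <- function(table, summarize = TRUE) {
  stopifnot(all(c("sample_id", "chrom", "range_bp") %in% names(table)))
  rel <- table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(med_r = stats::median(.data$range_bp)) |>
    dplyr::ungroup()
  bad <- rel$med_r <= 0 | !is.finite(rel$med_r)
  if (any(bad)) {
    warning(sprintf("excluding %d individual(s) with non-positive median range",
                    length(unique(rel$sample_id[bad]))))
    rel <- rel[!bad, ]
  }
  rel <- dplyr::mutate(rel, rel_range = .data$range_bp / .data$med_r)
  if (!summarize) {
    return(dplyr::select(rel, "sample_id", "chrom", "rel_range"))
  }
  rel |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(rel_range_median = stats::median(.data$rel_range),
                     n = dplyr::n(), .groups = "drop")
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `rho`, `ci_low`, `ci_high` and the two-sided `p`.
#' @export
spearman_with_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(length(x) - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rho = rho, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se),
       p = ct$p.value)
}

#' Relative CpG-island proportion per chromosome
#'
#' Fraction of probes flagged as CpG-island members per chromosome,
#' divided by the median fraction across chromosomes.
#'
#' @param manifest A manifest tibble with `chrom` and `island`.
#' @return A tibble with `chrom`, `prop_island`, `rel_prop`.
#' @export
island_proportions <- function(manifest) {
  stopifnot(all(c("chrom", "island") %in% names(manifest)))
  out <- manifest |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = dplyr::n(),
                     prop_island = mean(.data$island), .groups = "drop")
  if (any(out$n == 0)) {
    warning("excluding chromosome(s) with zero probes")
    out <- out[out$n > 0, ]
  }
  dplyr::mutate(dplyr::select(out, -"n"),
                rel_prop = .data$prop_island / stats::median(.data$prop_island))
}

#' Age-group contrast of the dependency parameters
#'
#' Splits individuals into a young (< `young_max` years) and an old
#' (> `old_min`) group and, per chromosome and parameter, runs a one-sided
#' Mann-Whitney test; per-parameter p-values are combined across
#' chromosomes with [combine_correlated_pvalues()], with the correlation
#' estimated from the per-individual chromosome profiles.
#'
#' @param table A parameter table joined to sample metadata (needs an
#'   `age` column; join the sample sheet first).
#' @param params Parameter columns to contrast.
#' @param young_max,old_min Age-group cut points (default 40 and 50).
#' @param direction `"young_greater"` (default; detects a downward shift
#'   in the old group) or `"old_greater"`.
#' @return A list with `per_chromosome` (tibble: param, chrom, group
#'   medians, p) and `combined` (tibble: param, p_combined, df, scale).
#' @export
age_group_contrast <- function(table,
                               params = c("post_mean_logtau", "post_mean_logkappa",
                                          "var_explained"),
                               young_max = 40, old_min = 50,
                               direction = c("young_greater", "old_greater")) {
  direction <- match.arg(direction)
  stopifnot("age" %in% names(table), all(params %in% names(table)))
  tab <- dplyr::mutate(table, age_group = dplyr::case_when(
    .data$age < young_max ~ "young",
    .data$age > old_min ~ "old",
    TRUE ~ NA_character_
  ))
  tab <- tab[!is.na(tab$age_group), ]
  if (!all(c("young", "old") %in% tab$age_group)) stop("one age group is empty")
  chroms <- sort(unique(tab$chrom))
  per_chrom <- list(); combined <- list()
  for (prm in params) {
    rows <- lapply(chroms, function(ch) {
      d <- tab[tab$chrom == ch, ]
      yg <- d[[prm]][d$age_group == "young"]
      og <- d[[prm]][d$age_group == "old"]
      mw <- if (direction == "young_greater") mann_whitney_one_sided(yg, og)
      else mann_whitney_one_sided(og, yg)
      tibble::tibble(param = prm, chrom = ch, n_young = length(yg),
                     n_old = length(og), median_young = stats::median(yg),
                     median_old = stats::median(og), p = mw$p)
    })
    rows <- dplyr::bind_rows(rows)
    est <- tab |>
      dplyr::select("sample_id", "chrom", dplyr::all_of(prm)) |>
      tidyr::pivot_wider(names_from = "chrom", values_from = dplyr::all_of(prm)) |>
      dplyr::select(-"sample_id")
    cmb <- combine_correlated_pvalues(rows$p, estimates = est)
    per_chrom[[prm]] <- rows
    combined[[prm]] <- tibble::tibble(param = prm, p_combined = cmb$p_combined,
                                      df = cmb$df, scale = cmb$scale)
  }
  list(per_chromosome = dplyr::bind_rows(per_chrom),
       combined = dplyr::bind_rows(combined))
}
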