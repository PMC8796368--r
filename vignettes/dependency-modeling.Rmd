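---
title: "Modeling spatial dependency in methylation residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatial dependency in methylation residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

DNA methylation measured on arrays is spatially dependent along each
chromosome: neighboring CpGs carry similar values, with the similarity
decaying over a scale of a few kilobases. `comethr` quantifies this
*co-methylation* per individual and per chromosome, on the residuals that
remain after removing each CpG's population mean and variance. Working on
residuals is what makes the quantity individual-specific: the strong
CpG-to-CpG differences in population mean would otherwise dominate any
correlation computed along the genome.

For one sample on one autosome, with residuals $y_p$ at base-pair
positions $p$:

$$
y_p \mid \mu_p, \sigma_0^2 \sim N(\mu_p, \sigma_0^2), \qquad
\mu = \beta + \xi, \qquad
\xi \sim N\!\left(0,\; \Sigma(\tau, \kappa)\right),
$$

where $\xi$ is a stationary 1-D Gaussian random field with Matérn
covariance

$$
\mathrm{Cov}(\xi(p_1), \xi(p_2)) =
\frac{\sigma^2}{\Gamma(\lambda)2^{\lambda-1}}
(\kappa d)^{\lambda} K_\lambda(\kappa d), \qquad d = |p_1 - p_2|.
$$

The smoothness is fixed at $\lambda = 1/2$, which makes the covariance
exactly exponential, $\sigma^2 e^{-\kappa d}$ — the shape empirical
correlation-vs-distance curves for array methylation follow. Two derived
parameters aid interpretation: the *range* $r = \sqrt{8\lambda}/\kappa$,
the distance at which correlation has decayed to roughly $0.1$, and the
marginal standard deviation $\sigma$ of the field. In one dimension

$$
\sigma^2 = \frac{\Gamma(\lambda)}
{\Gamma(\lambda + 1/2)\,(4\pi)^{1/2}\,\kappa^{2\lambda}\,\tau^2},
$$

which for $\lambda = 1/2$ collapses to $\sigma^2 = 1/(2\kappa\tau^2)$:
$\tau$ is a precision-like scale, with larger $\tau$ meaning a weaker
spatial signal. We use the $d=1$ normalization throughout because it is
the one under which the default prior calibration below is internally
consistent (range 3000 bp and $\sigma^2 = 1$ give
$\tau_m = \sqrt{750} = 27.39$ and $\kappa_m = 2/3000 = 0.00067$; the
$d=2$ normalization with $4\pi$ does not reproduce these values).

## Priors

`default_priors()` encodes a weakly informative set: $\beta \sim
N(0, 10^6)$, $1/\sigma_0^2 \sim \mathrm{Gamma}(1,\ 5\cdot10^{-5})$, and
Gaussians on $\log\tau$ and $\log\kappa$ with precision $0.05$ (variance
20) centered so that the prior field has range 3000 bp and marginal
variance 1. On population-normalized residuals the total variance is 1
by construction, so $\sigma^2 = 1$ is the natural prior scale and 3000 bp
sits inside the 1–3 kb window where methylation correlation is reported
to die off.

One consequence of this prior set is worth knowing: the Gamma(1,
$5\cdot10^{-5}$) prior is nearly flat on the *precision* scale up to
$2\cdot10^4$, so on the log scale its density keeps increasing toward
large precisions. When the data cannot distinguish field variance from
noise variance (pure-noise tracks), the posterior drifts toward tiny
$\sigma_0^2$ with a short-range field absorbing everything. The DIC
convention below is chosen to be robust to exactly this degeneracy.

## Inference: exact marginalization plus grid quadrature

Because the observation model is Gaussian and $\lambda = 1/2$ makes the
field a Markov process (an Ornstein–Uhlenbeck bridge on irregular
spacings), the latent field and the intercept can be integrated out
*exactly*: $(\xi_i, \beta)$ is a two-state linear-Gaussian state space
and a Kalman filter yields $\log p(y \mid \tau, \kappa, \sigma_0^2)$ in
$O(n)$. No finite-element approximation of the field is involved; the
tridiagonal precision of the observed sites (exposed as
`markov_precision()`) is inverted implicitly and exactly.

The three hyperparameters $(\log\tau, \log\kappa, \log 1/\sigma_0^2)$ get
a dense quadrature grid. The default grid is *mode-centered*: the
posterior mode is found by BFGS, axis scales come from the numerical
Hessian, and 11 nodes per dimension span the mode $\pm 4$ sd. We chose
this over a fixed grid spanning the prior mean $\pm 4$ *prior* sd because
the prior sd is $1/\sqrt{0.05} = 4.47$ log units: a fixed 21-node grid
would have node spacing 1.8 log units while the posterior sd at a few
hundred sites is 0.05–0.3, quantizing every posterior mean to the nearest
node. The fixed prior-spanning grid is still available
(`grid_config(strategy = "prior")`). If more than 5% of the posterior
mass lands on the outer grid shell, the grid is widened 1.5-fold and the
fit rerun (twice at most); a persistent overflow sets `boundary_flag`.

Posterior means and sds of $\log\tau$ and $\log\kappa$ are
weight-averaged node values. The reported $r$ and $\sigma$ are obtained
by transforming the posterior means of the log parameters — the
convention matching log-scale reporting — with node-wise transformation
and averaging available as `grid_config(transform = "node_mean")`.
Fits are fully deterministic: no randomness enters the inference.

## Model comparison by DIC

Each track is also fitted with the independence ("plain") model
$y_p \sim N(\beta, \sigma_0^2)$, same priors, and compared by DIC with
the conventional decisiveness threshold of 4. The deviance is that of the
observation model **with the latent field integrated out**, so its
parameters are $(\beta, \tau, \kappa, \sigma_0^2)$:
$\bar D$ is the posterior expectation of
$-2\log N(y;\ \beta 1,\ \sigma^2 e^{-\kappa\Delta} + \sigma_0^2 I)$,
$p_D = \bar D - D$ at the posterior mode, and $DIC = \bar D + p_D$. Two
properties motivated this flavor over a deviance conditional on the
field: (i) for the plain model it reduces to the classical case, with
$p_D \approx 2$ on iid data; and (ii) on pure-noise tracks, where the
posterior sits on the degenerate ridge described above, the
field-marginal likelihood equals the plain likelihood along the whole
ridge, so the comparison stays honest — a conditional-on-field deviance
instead rewards the noise-absorbing field with DIC differences of order
$5n$ on white noise. The plug-in point is the posterior *mode* rather
than the coordinate-wise mean because on ridge-shaped null posteriors the
mean falls off the ridge and produces negative $p_D$. The proportion of
residual variance captured by the field is reported as
$1 - \sigma_0^2(\text{dep})/\sigma_0^2(\text{plain})$, unclipped, so
slightly negative values on null data are visible rather than hidden.

## Preprocessing contract

`preprocess_methylation()` expects beta values that are already
probe-type normalized (design I/II harmonization is an established external
procedure and is deliberately not reimplemented). It applies the logit2
transform to M values, retains probes with call rate at least 95%,
standardizes each probe by its across-sample mean and unbiased sd, and
splits the result into per-(sample, chromosome) tracks, dropping missing
sites rather than imputing them — the model conditions only on observed
positions. The sd divisor uses $n-1$; the common wording ("mean and
variance") covers both conventions, and the unbiased one keeps the
$\sigma^2 = 1$ prior calibration coherent. Tracks with fewer than 50
observed sites are skipped: with a handful of sites the likelihood cannot
separate $(\tau, \kappa, \sigma_0)$ at all.

## Cohort statistics

The per-track posterior means feed five analyses:

* **ICC(1,1)** (one-way, absolute agreement, single unit) of $\log\tau$
  and $\log\kappa$, treating the 22 chromosomes as replicates and using
  one randomly selected individual per family (seeded selection) so twin
  resemblance does not masquerade as individual consistency.
* **Pairing contrasts**: squared differences
  $D = (\log\tau_A - \log\tau_B)^2$ per chromosome under four pairings —
  true twins, random, random matched on plate, random matched on plate
  and BeadChip. Random pairings exclude true co-twins (otherwise the
  contrasts are contaminated), are repeated 100 times, and the repeat of
  middle rank by median D represents the scheme. Group comparisons use a
  one-sided Mann–Whitney test per chromosome (midranks; exact enumeration
  for $m+n \le 20$, tie-corrected normal approximation otherwise).
* **Correlated combination**: per-chromosome p-values are combined with a
  scaled-$\chi^2$ extension of Fisher's method. With
  $X = -2\sum\ln p_j$, $E[X] = 2k$ and
  $\mathrm{Var}(X) = 4k + 2\sum_{i<j}\mathrm{cov}_{ij}$, where
  $\mathrm{cov}_{ij}$ follows the cubic polynomial
  $3.263\rho + 0.710\rho^2 + 0.027\rho^3$ in the between-chromosome
  correlation $\rho_{ij}$ of the tested statistic, estimated across
  units. The combined p is the upper tail of $c\chi^2_f$ with
  $c = \mathrm{Var}/2E$, $f = 2E^2/\mathrm{Var}$; at $\rho = 0$ this *is*
  Fisher's method, and at $\rho = 1$ with equal p-values it returns the
  single-test p.
* **Relative range**: each individual's $r$ estimates divided by their
  median across chromosomes, summarized per chromosome, with Spearman
  correlations (Fisher-z CIs, sd $1/\sqrt{n-3}$) against relative gene
  density and relative CpG-island proportion. Gene density is a
  user-supplied per-chromosome table; a synthetic fixture ships for
  examples and tests.
* **Age contrast**: young (< 40) versus old (> 50) distributions of
  $\log\tau$, $\log\kappa$ and variance explained, per chromosome, with
  one-sided Mann–Whitney tests combined as above.

## The synthetic cohort generator

`simulate_cohort()` is the package's test bed and null model. It draws,
in order: clustered CpG positions (dense islands of ~60 bp gaps inside a
~2.5 kb-gap background, island proportion varying by chromosome);
per-pair zygosity (55% MZ), a shared age group (26% older; ages about
N(62, 5) versus N(23, 3), an age gap with no individuals in between), and
sexes (MZ same-sex, 35% of DZ pairs opposite-sex); plate and BeadChip
assignments with co-twins always sharing a plate and sharing a chip with
probability 0.8; individual-level $(\log\tau, \log\kappa)$ with twin
correlation 0.9 (MZ) or 0.5 (DZ) around a population mean corresponding
to range 3000 bp and field variance 0.75 against noise sd 0.5 (so total
residual variance is about 1, matching the normalization); additive
plate (sd 0.3), chip (sd 0.18), sex (0.12) and old-age ($-0.3$ on
$\log\tau$) shifts, plus one deliberately outlying plate; per-chromosome
parameters spread sd 0.12 around the individual level; exact
Markov-property field draws plus noise; and finally population means from
a bimodal beta-scale distribution, residuals added on the M scale,
transformed back to beta values, with 1% missingness.

The effect sizes are synthetic: the study this emulates prints none, so
they were fixed once, at values a methylation batch-effect literature
reader would call plausible, and sized so that every cohort contrast is
detectable at 200 families — that detectability is itself part of the
test suite. Defaults simulate 6 chromosomes of 400 sites; the validation
suite and the reproduction script run at exactly these sizes. What the
generator does *not* emulate: probe-type chemistry, cell-composition
variation, genomic-context-dependent (island versus shore) dependency
differences, and methylation-age association beyond the single group
shift. A pass on synthetic data therefore validates the machinery and its
statistical calibration, not the biological claims, which require the
access-controlled cohort data.

## Numerical notes and limitations

* Positions must be strictly increasing; duplicate manifest positions are
  an error (the covariance would be singular) — deduplicate upstream.
* The likelihood is $O(n)$ per hyperparameter node; a 400-site track fits
  in ~30 ms, a 2000-site track in under a second.
* Quadrature error in posterior means is below 0.01 log units at the
  default 11 nodes (checked against a long Metropolis run on the dense
  covariance in the test suite, at tolerance 0.05).
* Hyperparameters of tracks with no spatial signal are weakly identified;
  their posterior means are dominated by the ridge geometry and should
  not be interpreted — only the DIC comparison is meaningful there.
* Non-Gaussian likelihoods, joint hierarchical fitting across chromosomes
  or individuals, and island-dependent $(\tau, \kappa)$ are out of scope.
* X/Y chromosomes are excluded by the manifest reader; the model is
  autosome-only.
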