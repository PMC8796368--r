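# comethr

Spatial dependency (co-methylation) modeling of array DNA methylation, per
individual and per chromosome, with cohort-level statistics for technical
and biological sources of variation.

Methylation at neighboring CpGs is correlated over a scale of a few
kilobases. `comethr` quantifies that dependency on the *residuals* left
after removing each CpG's population mean and variance, so the quantity is
specific to the individual rather than to the genomic background. For each
sample and autosome the residual track `y_p` at base-pair positions `p` is
modeled as a latent 1-D Gaussian field plus white noise:

    y_p ~ N(beta + xi_p, sigma0^2),     xi ~ GF(0, Sigma(tau, kappa))

with Matérn covariance at smoothness 1/2, i.e. exponential decay
`sigma^2 exp(-kappa d)`. The derived range `r = 2/kappa` is the distance at
which correlation drops to about 0.1, and `sigma^2 = 1/(2 kappa tau^2)` is
the field's marginal variance, so `tau` is a precision-like scale (large
`tau`, weak spatial signal). Because the exponential field is Markov, the
latent field and intercept are integrated out *exactly* by a Kalman filter
in O(n), and the posterior over `(log tau, log kappa, log 1/sigma0^2)` is
computed by adaptive grid quadrature — no spatial-approximation machinery
is involved. Each track is also fitted with an independence model
`y_p ~ N(beta, sigma0^2)` and the two are compared by DIC (difference > 4
decisive). Cohort statistics on the fitted parameter table cover ICC across
chromosome replicates, twin/plate/BeadChip pairing contrasts via squared
differences of the log parameters with one-sided Mann–Whitney tests and a
correlated-tests extension of Fisher's method, relative-range chromosome
profiles with Spearman correlations, and young-versus-old age contrasts.

A forward simulator (`simulate_cohort()`) generates full synthetic twin
cohorts — clustered CpG positions, MZ/DZ parameter correlation, plate and
BeadChip shifts, an age-group shift, missingness — with the ground truth
recorded, and is the basis of the package's validation.

## Worked example

```r
library(comethr)

# a synthetic cohort: 12 twin pairs, 3 chromosomes of 300 CpGs
cfg <- cohort_sim_config(n_families = 12, n_chromosomes = 3,
                         sites_per_chromosome = 300, seed = 42)
sim <- simulate_cohort(cfg)

# preprocessing: logit2 -> call-rate filter -> per-CpG standardization ->
# per-(sample, chromosome) residual tracks
tracks <- preprocess_methylation(sim$matrix, sim$manifest)

# one track, both models
tr  <- tracks$track[[1]]
dep <- fit_chromosome(tr)
dep
#> Dependency-model fit (sample S0001, chr 1, n = 292):
#>   log(tau)   3.412 (sd 0.165)    log(kappa) -6.629 (sd 0.319)
#>   range 1513 bp   sigma 0.642   sigma0^2 0.1037   beta -0.0691
#>   DIC 507.1 (p_D 4.0)   log evidence -274.5
compare_models(dep, fit_plain(tr))
#> $delta_dic
#> [1] 127.1656
#> $favored
#> [1] "dependency"
```

The fitted `log(kappa)` of −6.63 corresponds to a range of ~1.5 kb for
this individual, and the DIC difference of 127 decisively favors the
dependency model — on dependency-simulated data it essentially always
does, while on pure-noise tracks it does not. Fitting the whole cohort
and summarizing:

```r
fits   <- fit_cohort(tracks)       # one row per sample x chromosome
report <- cohort_report(fits, sim$sheet, manifest = sim$manifest, seed = 1)
report
#> Cohort dependency report: 72 fits, 24 samples
#>   ICC log(tau)   = 0.768 [0.519, 0.918]
#>   ICC log(kappa) = 0.367 [0.020, 0.720]
#>   Median D by pairing scheme (log tau):
#>     true_twins           0.0454
#>     random               0.1388
#>     matched_plate        0.1277
#>     matched_plate_chip   0.1806
#>   Pairing contrasts (combined p):
#>     matched_plate > true_twins               logtau   0.0602
#>     matched_plate_chip > true_twins          logtau   0.0159
#>     DZ > MZ                                  logtau   0.145
#>     ...
```

ICC near 0.77 says most variation in `log(tau)` estimates is between
individuals, not between chromosomes within an individual — the parameter
behaves as an individual trait. True co-twins are far more alike
(median squared difference 0.045) than any batch-matched pairing of
strangers, and the twins-versus-matched-strangers contrasts are already
the strongest signal at this toy size (combined p of 0.016–0.06 from 12
pairs). The finer distinctions — plate versus chip matching, DZ versus
MZ — need the validation scale of 200 families, where the full similarity
ordering (twins < plate+chip-matched < plate-matched < random) and the
zygosity and age contrasts all resolve (see the reproduction script
below). `plot_parameter_consistency()`, `plot_relative_range()` and
`plot_dependency_scatter()` give the corresponding figures, and
`tidy()`/`glance()` work on individual fits.

A thin command-line front end ships in `inst/exec/comethr`
(`simulate`, `fit`, `stats` subcommands) for running the pipeline on
files.

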