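# perisense

Structure–function analysis of mesopic retinal sensitivity around
geographic atrophy (GA) in age-related macular degeneration, for
researchers working with fundus-tracked microperimetry and reading-center
lesion annotations.

Macular regions inside GA are densely scotomatous, but sensitivity is also
depressed in the surrounding retina. `perisense` quantifies how sensitivity
varies with distance from the GA border across a longitudinal cohort:

* builds the fovea-centered **T-shaped testing grid** (40 loci: arms of 15°
  temporal, 12° superior, 12° inferior at 1° spacing) and handles the
  device units (0–20 dB attenuation relative to 127 cd/m²; 290 µm per
  degree);
* computes, per visit, the **Euclidean distance from each test locus to the
  nearest GA pixel** of a binary lesion mask, taking the minimum over
  lesions when the atrophy is multifocal;
* draws **LOESS curves** (span 0.5) of sensitivity against GA distance,
  overall, per axis, or per visit;
* fits the **segmented nonlinear mixed-effects model** at the heart of the
  analysis. For cluster *i* (one participant visit) and locus *j*:

  $$ y_{ij} = \mu(d_{ij}, t_i) + u_i + \varepsilon_{ij}, \qquad
     u_i \sim N(0,\sigma_u^2),\ \varepsilon_{ij} \sim N(0,\sigma_e^2) $$

  $$ \mu(d,t) = \beta_0 + \beta_t t + \begin{cases}
     b_1(k-d) + b_2(k-d)^2, & d < k\\
     b_3(d-k), & d \ge k\end{cases} $$

  where the knot *k* (the change-point between the steep perilesional rise
  and the gentle far-field slope) is estimated as a free parameter by exact
  marginal maximum likelihood, with Wald inference and delta-method
  interval-change contrasts;
* and provides a **synthetic-cohort generator** (growing multifocal star
  lesions, hierarchical noise, device rounding/censoring, optional 4-2
  staircase observer) so the entire chain is testable without any
  protected clinical data.

## Worked example

```r
library(perisense)

# the default parameters describe the published perilesional profile
p <- segmented_params()
sensitivity_mean(1, 0, p) - sensitivity_mean(0, 0, p)  # 2.96 dB from 0 to 1 deg
interval_change(p, 1.0)$estimate                       # 2.50 dB from 0.5 to 1.5 deg
interval_change(p, 1.5)$estimate                       # 2.04 dB from 1 to 2 deg
interval_change(p, 5.0)$estimate                       # 0.56 dB/deg beyond the knot

# simulate a study-condition cohort, annotate distances per visit, and fit
cfg <- simulation_config(rng_seed = 7)
cohort <- simulate_cohort(cfg)
ann <- annotate_dataset(cohort$records, cohort$masks, cfg$grid)
fit <- fit_segmented(ann)
print(fit)
```

```
Segmented sensitivity mixed model (4781 obs, 172 participant-visit clusters)
log-likelihood -12101.62, converged: TRUE
                        estimate     se ci_lower ci_upper
intercept                 7.0680 0.2451   6.5877   7.5483
time                     -0.0712 0.0099  -0.0905  -0.0519
ga_distance_before_knot  -1.9360 0.4895  -2.8954  -0.9767
ga_distance_quadratic    -0.0716 0.2691  -0.5990   0.4559
ga_distance_after_knot    0.5188 0.0178   0.4839   0.5537
knot                      1.9112 0.1110   1.6937   2.1287
sigma_u                   1.7587 0.1042   1.5546   1.9629
sigma_e                   2.9115 0.0303   2.8521   2.9709
```

The fit recovers the generating truth (time −0.07 dB/month, after-knot
slope 0.56 dB/°, knot 2.05°) from this cohort: sensitivity falls 0.07
dB/month at fixed distance, rises ~0.52 dB/° beyond ~1.9° from the border,
and rises much more steeply inside that perilesional zone. Fitted contrasts
come with delta-method intervals:

```r
interval_change(fit$estimates, m_deg = 0.5, vcov = fit$vcov)
# $estimate 2.14 dB per deg across [0, 1] deg   (95% CI 1.50, 2.78)
```

`run_pipeline()` executes the same chain end to end (validate → annotate →
curves → fit) and writes every artifact plus a run manifest;
`inst/cli/perisense.R` wraps it for shell use with `simulate`, `annotate`,
`curves`, `fit`, `validate` and `run` subcommands.

See `vignettes/perilesional-sensitivity.Rmd` for the model, the simulator's
assumptions, numerical choices, and known limitations (including the
upward-skewed small-sample behavior of the knot estimator).

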