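test_that("noise-free cohorts are recovered essentially exactly", {
  cfg <- simulation_config(n_participants = 8, raster_px = 256,
                           sigma_u = 1e-6, sigma_e = 1e-6, mode = "gaussian",
                           rng_seed = 3)
  co <- simulate_cohort(cfg)
  ann <- annotate_dataset(co$records, co$masks, build_t_grid())
  fit <- suppressWarnings(fit_segmented(ann))
  truth <- segmented_params()
  for (nm in c("beta0", "beta_t", "b1", "b2", "b3", "knot")) {
    expect_equal(fit$estimates[[nm]], truth[[nm]], tolerance = 1e-2,
                 label = nm)
  }
})

test_that("fits expose Wald machinery with consistent confidence intervals", {
  set.seed(22)
  ann <- direct_annotated(n_participants = 12, visit_months = c(0, 6, 12),
                          n_loci = 30)
  fit <- fit_segmented(ann)
  expect_true(fit$converged)
  expect_equal(fit$n_clusters, 36)
  expect_equal(unname(fit$ci95[, "upper"] - fit$ci95[, "lower"]),
               unname(2 * 1.96 * fit$se))
  # vcov symmetric with positive diagonal
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-6)
  expect_true(all(diag(fit$vcov) > 0))
  # the log-likelihood at the optimum matches the exported objective
  expect_equal(-fit$loglik, marginal_negloglik(fit$estimates, ann),
               tolerance = 1e-6)
  # interval-change contrasts at the fitted scale carry delta-method CIs
  ic <- interval_change(fit$estimates, 1, vcov = fit$vcov)
  expect_true(ic$ci95[1] < ic$estimate && ic$estimate < ic$ci95[2])
})

test_that("degenerate inputs are rejected", {
  set.seed(23)
  ann <- direct_annotated(n_participants = 1, visit_months = 0, n_loci = 20)
  expect_error(fit_segmented(ann), "clusters")
  ann2 <- direct_annotated(n_participants = 6, visit_months = 0, n_loci = 20,
                           d_max = 0.2)
  expect_error(fit_segmented(ann2), "span")
})

test_that("a knot estimate pinned at the search boundary warns", {
  set.seed(24)
  ann <- direct_annotated(n_participants = 10, visit_months = c(0, 6),
                          n_loci = 30, sigma_u = 0.3, sigma_e = 0.5)
  expect_warning(fit_segmented(ann, knot_range = c(0.25, 1)), "boundary")
})

test_that("replicate fits on model-simulated data recover the generating effects", {
  # moderate-size direct-design replicates: checks the estimator, not the
  # raster pipeline (covered elsewhere)
  set.seed(25)
  truth <- segmented_params()
  nrep <- 30
  est <- matrix(NA_real_, nrep, 5,
                dimnames = list(NULL, c("beta0", "beta_t", "b1", "b2", "b3")))
  for (r in seq_len(nrep)) {
    ann <- direct_annotated(n_participants = 12, visit_months = c(0, 9, 21),
                            n_loci = 30, params = truth, sigma_u = 2, sigma_e = 3)
    f <- suppressWarnings(fit_segmented(ann))
    est[r, ] <- unlist(f$estimates[colnames(est)])
  }
  bias <- colMeans(est) - unlist(truth[colnames(est)])
  mcse <- apply(est, 2, sd) / sqrt(nrep)
  for (nm in colnames(est)) {
    expect_lt(abs(bias[nm]), 3 * mcse[nm] + 1e-12, label = paste("bias of", nm))
  }
})

test_that("the foveal-distance coefficient is calibrated under the null", {
  set.seed(26)
  nrep <- 40
  covered <- logical(nrep)
  for (r in seq_len(nrep)) {
    ann <- direct_annotated(n_participants = 8, visit_months = c(0, 9),
                            n_loci = 25, sigma_u = 1.5, sigma_e = 2.5)
    f <- suppressWarnings(fit_with_foveal_covariate(ann))
    covered[r] <- abs(f$estimates$beta_f) < 2 * f$se[["beta_f"]]
  }
  expect_gte(mean(covered), 0.85)
})

test_that("a true foveal-distance effect is recovered without bias", {
  set.seed(27)
  truth <- segmented_params(beta_f = -0.3)
  nrep <- 25
  bf <- numeric(nrep)
  for (r in seq_len(nrep)) {
    ann <- direct_annotated(n_participants = 8, visit_months = c(0, 9),
                            n_loci = 25, params = truth,
                            sigma_u = 1.5, sigma_e = 2.5)
    f <- suppressWarnings(fit_with_foveal_covariate(ann))
    bf[r] <- f$estimates$beta_f
  }
  expect_lt(abs(mean(bf) + 0.3), 3 * sd(bf) / sqrt(nrep))
})

test_that("adding a null foveal covariate leaves the other estimates stable", {
  set.seed(28)
  diffs <- replicate(6, {
    ann <- direct_annotated(n_participants = 10, visit_months = c(0, 9),
                            n_loci = 30, sigma_u = 1.5, sigma_e = 2.5)
    f0 <- suppressWarnings(fit_segmented(ann))
    f1 <- suppressWarnings(fit_with_foveal_covariate(ann))
    nm <- c("beta_t", "b1", "b2", "b3")
    mean(abs(unlist(f1$estimates[nm]) - unlist(f0$estimates[nm])))
  })
  expect_lt(mean(diffs), 0.2)
})

test_that("fit reports are tabulated and written faithfully", {
  set.seed(29)
  ann <- direct_annotated(n_participants = 8, visit_months = c(0, 6),
                          n_loci = 25)
  fit <- suppressWarnings(fit_segmented(ann))
  rep <- fit_report(fit)
  expect_setequal(rep$term, c("intercept", "time", "ga_distance_before_knot",
                              "ga_distance_quadratic", "ga_distance_after_knot",
                              "knot", "sigma_u", "sigma_e"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, csv, js)
  back <- read.csv(csv)
  expect_equal(back$estimate, rep$estimate, tolerance = 1e-12)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$n_obs, fit$n_obs)
  # predicted curves follow the fitted mean
  pc <- predicted_curves(fit, months = c(0, 6), d_grid = c(0, 1, 3))
  expect_equal(pc$predicted_db[pc$visit_month == 0 & pc$ga_distance_deg == 1],
               sensitivity_mean(1, 0, fit$estimates))
})
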