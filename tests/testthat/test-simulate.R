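test_that("the 4-2 staircase converges within 2 dB for every integer threshold", {
  for (th in 0:20) {
    out <- staircase_4_2(th)
    expect_false(out$scotoma)
    expect_lte(abs(out$db - th), 2)
  }
  # starting exactly on the threshold returns it
  expect_equal(staircase_4_2(10)$db, 10)
})

test_that("sub-zero thresholds register as absolute scotomas", {
  out <- staircase_4_2(-3)
  expect_true(out$scotoma)
  expect_equal(out$db, 0)
  # a threshold above the dimmest stimulus pins at the ceiling
  expect_equal(staircase_4_2(25)$db, 20)
})

test_that("lesions are static when the growth rate is zero", {
  cfg <- simulation_config(n_participants = 2, visit_months = c(0, 6, 12),
                           growth_rate_deg_month = 0, raster_px = 128,
                           rng_seed = 3)
  masks <- simulate_lesions(cfg)
  for (p in c("P01", "P02")) {
    base <- masks[[mask_key(p, 0)]]$pixels
    expect_identical(masks[[mask_key(p, 6)]]$pixels, base)
    expect_identical(masks[[mask_key(p, 12)]]$pixels, base)
  }
})

test_that("sqrt lesion area grows linearly at the configured rate", {
  cfg <- simulation_config(n_participants = 3, visit_months = c(0, 12, 24, 45),
                           n_foci_range = c(1, 1), init_sqrt_area_deg = 4,
                           init_sqrt_area_sd = 0.5,
                           growth_rate_deg_month = 0.07,
                           raster_px = 256, rng_seed = 9)
  masks <- simulate_lesions(cfg)
  dpp <- 30 / 256
  for (p in sprintf("P%02d", 1:3)) {
    s0 <- sqrt(mask_area(masks[[mask_key(p, 0)]]))
    for (m in c(12, 24, 45)) {
      sm <- sqrt(mask_area(masks[[mask_key(p, m)]]))
      # rasterization error is on the order of the perimeter times one pixel
      expect_equal(sm, s0 + 0.07 * m, tolerance = 2.5 * dpp / (s0 + 0.07 * m))
    }
  }
})

test_that("a two-focus configuration yields two lesion components at baseline", {
  cfg <- simulation_config(n_participants = 1, visit_months = 0,
                           n_foci_range = c(2, 2), init_sqrt_area_deg = 2.5,
                           init_sqrt_area_sd = 0, raster_px = 128,
                           rng_seed = 12)
  masks <- simulate_lesions(cfg)
  expect_equal(count_components(masks[["P01@m0"]]$pixels), 2)
})

test_that("oversized lesions warn about field clipping", {
  cfg <- simulation_config(n_participants = 1, visit_months = 0,
                           n_foci_range = c(1, 1), init_sqrt_area_deg = 30,
                           init_sqrt_area_sd = 0, raster_px = 64, rng_seed = 1)
  expect_warning(simulate_lesions(cfg), "clipped")
})

test_that("noise-free rounded cohorts equal the clipped rounded mean", {
  cfg <- simulation_config(n_participants = 3, visit_months = c(0, 9),
                           sigma_u = 0, sigma_e = 0, raster_px = 128,
                           rng_seed = 21)
  co <- simulate_cohort(cfg)
  ex <- !co$truth$points$inside_ga
  expected <- pmin(pmax(round(co$truth$points$latent_mean[ex]), 0), 20)
  expect_equal(co$records$sensitivity_db[ex], expected)
  # intralesional loci are absolute scotomas at 0 dB
  expect_true(all(co$records$scotoma[!ex]))
  expect_true(all(co$records$sensitivity_db[!ex] == 0))
})

test_that("cohorts are deterministic given the configured seed", {
  cfg <- simulation_config(n_participants = 3, visit_months = c(0, 3, 9),
                           raster_px = 128, rng_seed = 33)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(lapply(a$masks, `[[`, "pixels"),
                   lapply(b$masks, `[[`, "pixels"))
  expect_identical(a$truth$clusters, b$truth$clusters)
})

test_that("generated sensitivities respect the device range and record caps", {
  cfg <- simulation_config(n_participants = 5, raster_px = 128, rng_seed = 14)
  co <- simulate_cohort(cfg)
  expect_true(all(co$records$sensitivity_db >= 0 & co$records$sensitivity_db <= 20))
  expect_true(all(co$records$sensitivity_db == round(co$records$sensitivity_db)))
  expect_true(all(co$records$sensitivity_db[co$records$scotoma] == 0))
  per <- table(co$records$participant_id)
  visits <- tapply(co$records$visit_month, co$records$participant_id,
                   function(v) length(unique(v)))
  expect_true(all(per <= 40 * visits[names(per)]))
})

test_that("cluster noise has compound-symmetry covariance", {
  # many clusters, known truth; off-diagonal covariance ~ sigma_u^2 and
  # diagonal ~ sigma_u^2 + sigma_e^2
  cfg <- simulation_config(n_participants = 40, visit_months = c(0, 3, 9),
                           dropout_prob = 0, sigma_u = 2, sigma_e = 3,
                           mode = "gaussian", raster_px = 128, rng_seed = 8)
  co <- simulate_cohort(cfg)
  pts <- co$truth$points
  resid <- pts$latent_threshold - pts$latent_mean
  cl <- paste(pts$participant_id, pts$visit_month)
  n_cl <- length(unique(cl))
  var_tot <- mean(tapply(resid, cl, function(r) mean(r^2)))
  cov_off <- mean(tapply(resid, cl, function(r) {
    s <- sum(r); n <- length(r)
    (s^2 - sum(r^2)) / (n * (n - 1))
  }))
  expect_equal(cov_off, 4, tolerance = 0.35) # ~4 MC SEs of the cluster mean
  expect_equal(var_tot, 13, tolerance = 0.12)
})

test_that("sensitivity rises with distance from GA in a default cohort", {
  cfg <- simulation_config(raster_px = 256, rng_seed = 26)
  co <- simulate_cohort(cfg)
  ann <- annotate_dataset(co$records, co$masks, build_t_grid())
  base <- ann[ann$visit_month == 0 & !ann$inside_ga, ]
  far <- mean(base$sensitivity_db[base$ga_distance_deg >= 4])
  near <- mean(base$sensitivity_db[base$ga_distance_deg < 1])
  expect_gt(far, near)
})

test_that("the empty cohort degenerates gracefully", {
  co <- simulate_cohort(simulation_config(n_participants = 0, raster_px = 64))
  expect_equal(nrow(co$records), 0)
  expect_length(co$masks, 0)
})
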