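make_point_mask <- function(npx, ga_rc, deg_per_pixel = 0.1, fovea = NULL,
                            month = 0, pid = "A") {
  px <- matrix(FALSE, npx, npx)
  px[ga_rc] <- TRUE
  lesion_mask(px, deg_per_pixel = deg_per_pixel, fovea_px = fovea,
              visit_month = month, participant_id = pid)
}

test_that("distance to a single GA pixel follows plane geometry", {
  # fovea at pixel (10, 10); GA pixel 3 right and 4 down from the locus pixel
  px <- matrix(FALSE, 21, 21)
  px[10 + 4 + 1, 10 + 3 + 1] <- TRUE # 0-based (13, 14) -> row 15, col 14
  m <- lesion_mask(px, deg_per_pixel = 0.1, visit_month = 0, participant_id = "A")
  locus <- data.frame(x_deg = 0, y_deg = 0) # at the fovea pixel (10, 10)
  expect_equal(distance_to_ga(locus, m), 0.5) # 3-4-5 triangle at 0.1 deg/px
})

test_that("a locus on a GA pixel is intralesional with distance zero", {
  m <- make_point_mask(21, cbind(11, 11)) # GA at the fovea pixel
  expect_equal(distance_to_ga(data.frame(x_deg = 0, y_deg = 0), m), 0)
})

test_that("distance equals the exhaustive all-pixel oracle on random multifocal masks", {
  set.seed(7)
  for (rep in 1:8) {
    npx <- sample(c(48, 64, 128), 1)
    m <- random_mask(npx = npx, n_lesions = 2, deg_per_pixel = 30 / 768)
    half <- (npx / 2 - 1) * m$deg_per_pixel
    loci <- data.frame(x_deg = runif(10, -half, half),
                       y_deg = runif(10, -half, half))
    expect_equal(distance_to_ga(loci, m), oracle_distance(loci, m),
                 tolerance = 1e-9)
  }
})

test_that("distance is monotone under lesion growth and respects the union rule", {
  set.seed(11)
  m1 <- random_mask(64, n_lesions = 1)
  m2 <- random_mask(64, n_lesions = 1)
  mu <- lesion_mask(m1$pixels | m2$pixels, deg_per_pixel = m1$deg_per_pixel,
                    visit_month = 0, participant_id = "X")
  loci <- data.frame(x_deg = runif(12, -2.5, 2.5), y_deg = runif(12, -2.5, 2.5))
  d1 <- distance_to_ga(loci, m1)
  d2 <- distance_to_ga(loci, m2)
  du <- distance_to_ga(loci, mu)
  # union of lesions: minimum across the two
  expect_equal(du, pmin(d1, d2), tolerance = 1e-12)
  # adding GA pixels can only shrink distances
  expect_true(all(du <= d1 + 1e-12))
})

test_that("empty masks and out-of-field loci raise classed errors", {
  empty <- lesion_mask(matrix(FALSE, 16, 16), visit_month = 0,
                       participant_id = "A")
  expect_error(distance_to_ga(data.frame(x_deg = 0, y_deg = 0), empty),
               class = "perisense_no_lesion_error")
  m <- make_point_mask(16, cbind(3, 3))
  expect_error(distance_to_ga(data.frame(x_deg = 5, y_deg = 0), m),
               class = "perisense_out_of_field_error")
})

test_that("annotation joins per-visit masks with hand-computed distances", {
  # two visits; lesion is one pixel at baseline, grows a second pixel closer
  # to the temporal locus at month 6
  dpp <- 0.5
  fovea <- c(x = 8, y = 8)
  m0 <- make_point_mask(17, cbind(9, 13), dpp, fovea, 0, "P1")  # 0-based (12, 8)
  px <- matrix(FALSE, 17, 17); px[9, 13] <- TRUE; px[9, 15] <- TRUE
  m6 <- lesion_mask(px, deg_per_pixel = dpp, fovea_px = fovea,
                    visit_month = 6, participant_id = "P1")
  grid <- build_t_grid(3, 1, 1, 1)
  recs <- data.frame(participant_id = "P1",
                     visit_month = rep(c(0, 6), each = 3),
                     locus_id = rep(c(0L, 3L, 4L), 2), # center, temporal 3, superior 1
                     sensitivity_db = 10, scotoma = FALSE)
  ann <- annotate_dataset(recs, list(m0, m6), grid)
  # GA pixel at 0-based (x=12, y=8): 2 deg temporal of fovea on the meridian
  expect_equal(ann$ga_distance_deg[ann$visit_month == 0 & ann$locus_id == 0], 2)
  expect_equal(ann$ga_distance_deg[ann$visit_month == 0 & ann$locus_id == 3], 1)
  expect_equal(ann$ga_distance_deg[ann$visit_month == 0 & ann$locus_id == 4],
               sqrt(2^2 + 1^2))
  # month 6 adds GA at (x=14, y=8): 3 deg temporal, touching locus 3
  expect_equal(ann$ga_distance_deg[ann$visit_month == 6 & ann$locus_id == 3], 0)
  expect_true(ann$inside_ga[ann$visit_month == 6 & ann$locus_id == 3])
  # distances never increase when the lesion only grows
  d0 <- ann$ga_distance_deg[ann$visit_month == 0]
  d6 <- ann$ga_distance_deg[ann$visit_month == 6]
  expect_true(all(d6 <= d0 + 1e-12))
  # foveal distance comes from the grid geometry
  expect_equal(ann$foveal_distance_deg[ann$locus_id == 0], c(0, 0))
  expect_equal(ann$foveal_distance_deg[ann$locus_id == 3], c(3, 3))
})

test_that("a missing mask is reported with its participant-visit key", {
  m0 <- make_point_mask(17, cbind(9, 13), 0.5, NULL, 0, "P1")
  recs <- data.frame(participant_id = "P1", visit_month = c(0, 6),
                     locus_id = 0L, sensitivity_db = 5, scotoma = FALSE)
  expect_error(annotate_dataset(recs, list(m0), build_t_grid(3, 1, 1, 1)),
               "P1@m6", class = "perisense_missing_mask_error")
})

test_that("masks round-trip through PNG and text with their sidecars", {
  set.seed(5)
  m <- random_mask(32, n_lesions = 2)
  m$participant_id <- "P9"; m$visit_month <- 15
  for (ext in c(".png", ".txt")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mask(m, path)
    m2 <- read_mask(path)
    expect_equal(m2$pixels, m$pixels)
    expect_equal(m2$deg_per_pixel, m$deg_per_pixel)
    expect_equal(m2$fovea_px, m$fovea_px)
    expect_equal(m2$visit_month, 15)
    expect_equal(m2$participant_id, "P9")
  }
})
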