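#' Configuration for synthetic longitudinal cohorts
#'
#' Describes the study conditions the generator emulates: a cohort of
#' participants tested on the 40-locus T-grid at baseline, month 3 and every
#' 6 months thereafter, with growing (possibly multifocal) GA lesions,
#' sensitivities drawn from the segmented model with a participant-visit
#' random intercept, and floor/ceiling censoring of the 0-20 dB device
#' range.
#'
#' Lesion sizes are drawn per participant from a truncated normal on the
#' square root of lesion area (defaults correspond to a typical GA cohort:
#' mean sqrt-area ~2.6 mm, SD ~1.0 mm, at 290 um/degree). Lesions grow so
#' that the square root of total area increases linearly in time at
#' `growth_rate_deg_month` (default 0.07 degrees/month, ~0.24 mm/year).
#' Participants attend baseline and then drop out permanently with
#' probability `dropout_prob` at each subsequent scheduled visit, giving a
#' realistic mean of ~5 attended visits out of 9.
#'
#' @param n_participants Number of participants (default 26).
#' @param visit_months Scheduled visit months, strictly increasing from 0.
#' @param dropout_prob Per-transition permanent dropout probability in
#'   `[0, 1]`.
#' @param true_params Generating [segmented_params()] (fixed effects).
#' @param sigma_u Participant-visit random-intercept SD in dB.
#' @param sigma_e Residual SD in dB.
#' @param n_foci_range Integer range of lesion foci per participant.
#' @param init_sqrt_area_deg,init_sqrt_area_sd Mean and SD (degrees) of the
#'   baseline sqrt lesion area across participants.
#' @param growth_rate_deg_month Growth of sqrt-area, degrees/month.
#' @param raster_px Mask raster size in pixels (square; default 768).
#' @param field_deg Imaging field width in degrees (default 30).
#' @param mode Measurement model: `"gaussian_rounded"` (Gaussian noise,
#'   rounded to integer dB and censored to the device range; the study
#'   condition), `"staircase_4_2"` (deterministic 4-2 staircase observer on
#'   the noisy latent threshold), or `"gaussian"` (no rounding or censoring;
#'   for estimator validation, where simulation must follow the model the
#'   fit assumes).
#' @param grid Testing grid; default [build_t_grid()].
#' @param rng_seed Integer seed; the entire cohort is deterministic given
#'   the config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 26,
                              visit_months = c(0, 3, seq(9, 45, by = 6)),
                              dropout_prob = 0.15,
                              true_params = segmented_params(),
                              sigma_u = 2, sigma_e = 3,
                              n_foci_range = c(1L, 3L),
                              init_sqrt_area_deg = 9,
                              init_sqrt_area_sd = 3.4,
                              growth_rate_deg_month = 0.07,
                              raster_px = 768, field_deg = 30,
                              mode = c("gaussian_rounded", "staircase_4_2",
                                       "gaussian"),
                              grid = build_t_grid(),
                              rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_participants >= 0, length(visit_months) >= 1,
            visit_months[1] == 0, !is.unsorted(visit_months, strictly = TRUE),
            dropout_prob >= 0, dropout_prob <= 1,
            inherits(true_params, "segmented_params"),
            sigma_u >= 0, sigma_e >= 0,
            n_foci_range[1] >= 1, n_foci_range[2] >= n_foci_range[1],
            init_sqrt_area_deg > 0, growth_rate_deg_month >= 0,
            raster_px >= 16, field_deg > 0)
  structure(list(n_participants = as.integer(n_participants),
                 visit_months = as.numeric(visit_months),
                 dropout_prob = dropout_prob, true_params = true_params,
                 sigma_u = sigma_u, sigma_e = sigma_e,
                 n_foci_range = as.integer(n_foci_range),
                 init_sqrt_area_deg = init_sqrt_area_deg,
                 init_sqrt_area_sd = init_sqrt_area_sd,
                 growth_rate_deg_month = growth_rate_deg_month,
                 raster_px = as.integer(raster_px), field_deg = field_deg,
                 mode = mode, grid = grid, rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Latent mean sensitivity of the generator
#'
#' Thin wrapper over [sensitivity_mean()] so the simulator and the model
#' share a single mean function.
#'
#' @inheritParams sensitivity_mean
#' @return Mean sensitivity in dB.
#' @export
latent_sensitivity <- function(d_deg, t_months, params, foveal_deg = NULL) {
  sensitivity_mean(d_deg, t_months, params, foveal_deg = foveal_deg)
}

# ---- lesion geometry -------------------------------------------------------

# per-participant lesion geometry: foci centers, area weights, and a fixed
# 8-harmonic radial perturbation per focus
draw_lesion_geometry <- function(config) {
  n_foci <- if (config$n_foci_range[1] == config$n_foci_range[2])
    config$n_foci_range[1] else
      sample(seq(config$n_foci_range[1], config$n_foci_range[2]), 1L)
  s0 <- stats::rnorm(1, config$init_sqrt_area_deg, config$init_sqrt_area_sd)
  lo <- max(1, config$init_sqrt_area_deg - 2 * config$init_sqrt_area_sd)
  hi <- config$init_sqrt_area_deg + 2 * config$init_sqrt_area_sd
  s0 <- min(max(s0, lo), hi)
  w <- stats::runif(n_foci, 0.3, 1); w <- w / sum(w)
  foci <- lapply(seq_len(n_foci), function(i) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0.5, 4) # parafoveal seed location
    amp <- stats::rnorm(8, 0, 0.04) * (2 / seq_len(8))
    phase <- stats::runif(8, 0, 2 * pi)
    list(cx = rad * cos(ang), cy = rad * sin(ang), weight = w[i],
         amp = amp, phase = phase)
  })
  list(foci = foci, sqrt_area0 = s0)
}

# area of one star blob with base radius r0: pi r0^2 (1 + sum(amp^2)/2)
blob_base_radius <- function(area, amp) {
  sqrt(area / (pi * (1 + sum(amp^2) / 2)))
}

# render the geometry at one visit month onto a raster
render_lesion <- function(geom, month, config) {
  s_m <- geom$sqrt_area0 + config$growth_rate_deg_month * month
  gscale <- s_m / geom$sqrt_area0
  npx <- config$raster_px
  dpp <- config$field_deg / npx
  px <- matrix(FALSE, npx, npx)
  fovea <- c(x = (npx - 1) / 2, y = (npx - 1) / 2)
  clipped <- FALSE
  for (f in geom$foci) {
    area_f <- f$weight * s_m^2
    r0 <- blob_base_radius(area_f, f$amp) * 1 # degrees
    rmax <- r0 * (1 + sum(abs(f$amp)))
    # bounding box in pixels (image rows grow downward)
    cx_px <- fovea["x"] + f$cx / dpp
    cy_px <- fovea["y"] - f$cy / dpp
    half <- ceiling(rmax / dpp) + 1
    xs <- floor(cx_px - half):ceiling(cx_px + half)
    ys <- floor(cy_px - half):ceiling(cy_px + half)
    if (any(xs < 0) || any(xs > npx - 1) || any(ys < 0) || any(ys > npx - 1))
      clipped <- TRUE
    xs <- xs[xs >= 0 & xs <= npx - 1]
    ys <- ys[ys >= 0 & ys <= npx - 1]
    if (!length(xs) || !length(ys)) next
    dx <- (xs - cx_px) * dpp
    dy <- -(ys - cy_px) * dpp # back to retinal +y = superior
    DX <- matrix(dx, length(ys), length(xs), byrow = TRUE)
    DY <- matrix(dy, length(ys), length(xs))
    r <- sqrt((DX - 0)^2 + (DY - 0)^2)
    th <- atan2(DY, DX)
    pert <- 0
    for (h in seq_len(8)) pert <- pert + f$amp[h] * cos(h * th + f$phase[h])
    inside <- r <= r0 * pmax(1 + pert, 0.2)
    px[ys + 1, xs + 1] <- px[ys + 1, xs + 1] | inside
  }
  if (clipped)
    warning("lesion extends beyond the imaging field and was clipped")
  list(pixels = px, deg_per_pixel = dpp, fovea_px = fovea)
}

#' Simulate growing lesion masks for a cohort
#'
#' Draws per-participant lesion geometry (1-3 star-shaped foci near the
#' fovea with a low-order radial Fourier perturbation) and renders one
#' binary mask per participant and scheduled visit, scaled so that the
#' square root of total lesion area grows linearly in time.
#'
#' @param config A [simulation_config()]; `config$rng_seed` makes the output
#'   deterministic.
#' @return Named list of [lesion_mask()] objects (one per participant-visit).
#' @export
simulate_lesions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  masks <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    geom <- draw_lesion_geometry(config)
    for (m in config$visit_months) {
      r <- render_lesion(geom, m, config)
      masks[[mask_key(pid, m)]] <-
        lesion_mask(r$pixels, deg_per_pixel = r$deg_per_pixel,
                    fovea_px = r$fovea_px, visit_month = m,
                    participant_id = pid)
    }
  }
  masks
}

# ---- measurement -----------------------------------------------------------

#' Simulate a 4-2 staircase threshold measurement
#'
#' Deterministic-observer staircase: the stimulus starts at `start_db`
#' attenuation and the observer responds whenever the presented attenuation
#' does not exceed the true threshold. Seen stimuli step 4 dB dimmer, unseen
#' 4 dB brighter, until the first reversal; steps of 2 dB then continue
#' until the second reversal. The measured sensitivity is the last-seen
#' attenuation, clipped to the device range. A threshold below 0 dB yields
#' an absolute scotoma (no response at maximum intensity): value 0 with the
#' scotoma flag set.
#'
#' @param true_threshold_db True threshold in dB (may lie outside `[0, 20]`).
#' @param start_db Starting attenuation (default 10).
#' @return List with `db` (measured value) and `scotoma` (logical).
#' @export
staircase_4_2 <- function(true_threshold_db, start_db = 10) {
  stopifnot(start_db >= 0, start_db <= 20)
  level <- start_db
  step <- 4
  reversals <- 0L
  dir <- 0L
  last_seen <- NA_real_
  for (iter in 1:100) {
    seen <- level <= true_threshold_db
    if (seen) last_seen <- level
    newdir <- if (seen) 1L else -1L
    if (dir != 0L && newdir != dir) {
      reversals <- reversals + 1L
      if (reversals == 2L) break
      step <- 2
    }
    dir <- newdir
    nxt <- min(max(level + newdir * step, 0), 20)
    if (nxt == level) { # pinned at a device limit
      if (!seen && level == 0) return(list(db = 0, scotoma = TRUE))
      if (seen && level == 20) return(list(db = 20, scotoma = FALSE))
      break
    }
    level <- nxt
  }
  if (is.na(last_seen)) return(list(db = 0, scotoma = TRUE))
  list(db = min(max(last_seen, 0), 20), scotoma = FALSE)
}

# ---- cohort ----------------------------------------------------------------

#' Simulate a longitudinal microperimetry cohort
#'
#' Generates, per retained participant-visit: one lesion mask, one draw of
#' the cluster random intercept `u ~ N(0, sigma_u^2)`, and one sensitivity
#' record per grid locus. Extralesional loci get true threshold
#' `mean(d, t) + u + N(0, sigma_e^2)` passed through the configured
#' measurement model; intralesional loci are emitted as absolute scotomas
#' (value 0). The truth tables record the cluster effects and per-point
#' latent quantities for recovery testing.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (sensitivity records), `masks` (named list of
#'   [lesion_mask()]), and `truth` (list: `params`, `sigma_u`, `sigma_e`,
#'   `clusters` data frame with the random intercepts, `points` data frame
#'   with per-record distance and latent threshold).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  grid <- config$grid
  nloc <- nrow(grid)
  masks <- list()
  rec <- list(); cl <- list(); pts <- list()

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    geom <- draw_lesion_geometry(config)
    # permanent dropout after baseline
    attended <- config$visit_months[1]
    for (m in config$visit_months[-1]) {
      if (stats::runif(1) < config$dropout_prob) break
      attended <- c(attended, m)
    }
    for (m in attended) {
      r <- render_lesion(geom, m, config)
      mk <- lesion_mask(r$pixels, deg_per_pixel = r$deg_per_pixel,
                        fovea_px = r$fovea_px, visit_month = m,
                        participant_id = pid)
      masks[[mask_key(pid, m)]] <- mk
      d <- distance_to_ga(grid, mk)
      inside <- is_inside_ga(grid, mk)
      d[inside] <- 0
      u <- stats::rnorm(1, 0, config$sigma_u)
      mu <- latent_sensitivity(d, m, config$true_params)
      latent <- mu + u + stats::rnorm(nloc, 0, config$sigma_e)

      meas <- measure(latent, config$mode)
      meas$db[inside] <- 0
      meas$scotoma[inside] <- TRUE

      rec[[length(rec) + 1L]] <- data.frame(
        participant_id = pid, visit_month = m, locus_id = grid$locus_id,
        axis = grid$axis, axis_orientation = axis_orientation(grid$axis),
        sensitivity_db = meas$db, scotoma = meas$scotoma,
        stringsAsFactors = FALSE)
      cl[[length(cl) + 1L]] <- data.frame(
        participant_id = pid, visit_month = m, u = u,
        stringsAsFactors = FALSE)
      pts[[length(pts) + 1L]] <- data.frame(
        participant_id = pid, visit_month = m, locus_id = grid$locus_id,
        ga_distance_deg = d, inside_ga = inside, latent_mean = mu,
        latent_threshold = latent, stringsAsFactors = FALSE)
    }
  }

  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(participant_id = character(), visit_month = numeric(),
               locus_id = integer(), axis = character(),
               axis_orientation = character(), sensitivity_db = numeric(),
               scotoma = logical())
  list(records = records, masks = masks,
       truth = list(params = config$true_params, sigma_u = config$sigma_u,
                    sigma_e = config$sigma_e,
                    clusters = if (length(cl)) do.call(rbind, cl) else NULL,
                    points = if (length(pts)) do.call(rbind, pts) else NULL))
}

# apply the measurement model to a vector of latent thresholds
measure <- function(latent, mode) {
  if (mode == "gaussian") {
    list(db = latent, scotoma = rep(FALSE, length(latent)))
  } else if (mode == "gaussian_rounded") {
    db <- pmin(pmax(round(latent), 0), 20)
    list(db = db, scotoma = db == 0 & latent < 0)
  } else { # staircase_4_2
    out <- lapply(latent, staircase_4_2)
    list(db = vapply(out, `[[`, numeric(1), "db"),
         scotoma = vapply(out, `[[`, logical(1), "scotoma"))
  }
}

#' Write simulated records to CSV
#'
#' @param records Records data frame from [simulate_cohort()].
#' @param path Output path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
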