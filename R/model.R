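#' Parameters of the segmented sensitivity model
#'
#' Parameterizes the mean mesopic sensitivity (dB) of an extralesional locus
#' as a function of its distance `d` (degrees) from the GA border and time
#' `t` (months since baseline):
#'
#' \deqn{\mu(d, t) = \beta_0 + \beta_t t + \begin{cases}
#'   b_1 (k - d) + b_2 (k - d)^2 & d < k \\
#'   b_3 (d - k)                 & d \ge k \end{cases}}
#'
#' Both segment bases vanish at `d = k`, so the mean is continuous at the
#' knot by construction. An optional foveal-distance covariate adds
#' `beta_f * foveal_deg`. With the default coefficients, sensitivity rises
#' steeply (and quadratically, concave down) within about 2 degrees of the
#' border and by about 0.56 dB per degree beyond it, and declines by 0.07 dB
#' per month at a fixed distance; the defaults are the generative truth used
#' by [simulate_cohort()].
#'
#' `sigma_u` and `sigma_e` are the participant-visit random-intercept and
#' residual standard deviations of the mixed model (compound-symmetry
#' covariance within a participant-visit cluster).
#'
#' @param beta0 Intercept: mean sensitivity at the knot at baseline (dB).
#' @param beta_t Time slope (dB/month).
#' @param b1 Before-knot coefficient on `(k - d)` (dB/degree).
#' @param b2 Before-knot coefficient on `(k - d)^2` (dB/degree^2).
#' @param b3 After-knot slope on `(d - k)` (dB/degree).
#' @param knot Change-point distance `k` in degrees (> 0).
#' @param beta_f Optional foveal-distance coefficient (dB/degree); `NULL`
#'   disables the covariate.
#' @param sigma_u Random-intercept SD (dB, >= 0).
#' @param sigma_e Residual SD (dB, > 0).
#' @return An object of class `segmented_params`.
#' @examples
#' p <- segmented_params()
#' sensitivity_mean(1, 0, p) - sensitivity_mean(0, 0, p) # about 2.96 dB
#' @export
segmented_params <- function(beta0 = 7, beta_t = -0.07, b1 = -1.53,
                             b2 = -0.46, b3 = 0.56, knot = 2.05,
                             beta_f = NULL, sigma_u = 2, sigma_e = 3) {
  stopifnot(is.numeric(knot), length(knot) == 1L)
  if (knot <= 0) stop("knot must be > 0")
  if (sigma_u < 0) stop("sigma_u must be >= 0")
  if (sigma_e <= 0) stop("sigma_e must be > 0")
  structure(list(beta0 = beta0, beta_t = beta_t, b1 = b1, b2 = b2, b3 = b3,
                 knot = knot, beta_f = if (is.null(beta_f)) NULL else beta_f,
                 sigma_u = sigma_u, sigma_e = sigma_e),
            class = "segmented_params")
}

#' @export
print.segmented_params <- function(x, ...) {
  cat("segmented sensitivity model parameters\n")
  cat(sprintf("  intercept %.3f dB, time %.3f dB/month, knot %.3f deg\n",
              x$beta0, x$beta_t, x$knot))
  cat(sprintf("  before knot: %.3f (k-d) %+.3f (k-d)^2; after knot: %.3f (d-k)\n",
              x$b1, x$b2, x$b3))
  if (!is.null(x$beta_f)) cat(sprintf("  foveal distance: %.3f dB/deg\n", x$beta_f))
  cat(sprintf("  sigma_u %.3f dB, sigma_e %.3f dB\n", x$sigma_u, x$sigma_e))
  invisible(x)
}

#' Mean of the segmented sensitivity model
#'
#' Evaluates the fixed-effect mean described in [segmented_params()]:
#' quadratic in GA distance below the knot, linear above it, linear in time,
#' with an optional foveal-distance term.
#'
#' @param d_deg GA distance in degrees (>= 0); vectorized.
#' @param t_months Months since baseline; vectorized.
#' @param params A [segmented_params()].
#' @param foveal_deg Foveal distance in degrees; required when `params`
#'   carries `beta_f`.
#' @return Mean sensitivity in dB.
#' @export
sensitivity_mean <- function(d_deg, t_months, params, foveal_deg = NULL) {
  stopifnot(inherits(params, "segmented_params"))
  if (any(d_deg < 0, na.rm = TRUE)) stop("d_deg must be non-negative")
  k <- params$knot
  before <- d_deg < k
  seg <- ifelse(before,
                params$b1 * (k - d_deg) + params$b2 * (k - d_deg)^2,
                params$b3 * (d_deg - k))
  mu <- params$beta0 + params$beta_t * t_months + seg
  if (!is.null(params$beta_f)) {
    if (is.null(foveal_deg))
      stop("params carry a foveal-distance coefficient; supply foveal_deg")
    mu <- mu + params$beta_f * foveal_deg
  }
  mu
}

#' Sensitivity change over a 1-degree (or custom) distance interval
#'
#' Computes the model-implied change in mean sensitivity when GA distance
#' increases across the interval centered at `m_deg` with the given width,
#' holding time constant. Within one segment the change has a closed form:
#' below the knot it is `(-b1 - 2 b2 (k - m)) * width` (so the per-degree
#' change grows as the border is approached when `b2 < 0`); at or above the
#' knot it is `b3 * width`. Intervals that straddle the knot are computed by
#' direct differencing of the mean function.
#'
#' When the covariance matrix of a fit is supplied, a delta-method standard
#' error and 95% Wald interval are attached (gradient derived analytically
#' for the closed forms, numerically for straddling intervals).
#'
#' @param params A [segmented_params()] (or the `estimates` of a fit).
#' @param m_deg Interval midpoint in degrees.
#' @param width Interval width in degrees (default 1).
#' @param vcov Optional covariance matrix with rows/columns named as in
#'   [fit_segmented()] (`"b1"`, `"b2"`, `"b3"`, `"knot"`, ...).
#' @param method `"auto"` picks the closed form when the interval lies in
#'   one segment; `"closed"` errors on straddling intervals; `"direct"`
#'   always differences the mean function.
#' @return A list with `estimate` (dB) and, when `vcov` is given, `se` and
#'   `ci95`.
#' @export
interval_change <- function(params, m_deg, width = 1, vcov = NULL,
                            method = c("auto", "closed", "direct")) {
  stopifnot(inherits(params, "segmented_params"), length(m_deg) == 1L)
  method <- match.arg(method)
  k <- params$knot
  lo <- m_deg - width / 2
  hi <- m_deg + width / 2
  if (lo < 0) stop("interval extends below 0 degrees")
  straddles <- lo < k && hi > k
  if (straddles && method == "closed")
    stop(errorCondition(
      "interval straddles the knot; use direct mean-function differencing",
      class = c("perisense_knot_straddle_error", "error", "condition")))

  if (!straddles && method != "direct") {
    if (hi <= k) { # fully below the knot
      est <- (-params$b1 - 2 * params$b2 * (k - m_deg)) * width
      grad <- c(b1 = -width, b2 = -2 * (k - m_deg) * width,
                knot = -2 * params$b2 * width)
    } else { # fully at/above the knot
      est <- params$b3 * width
      grad <- c(b3 = width)
    }
  } else {
    est <- sensitivity_mean(hi, 0, strip_foveal(params),
                            foveal_deg = NULL) -
      sensitivity_mean(lo, 0, strip_foveal(params), foveal_deg = NULL)
    grad <- numeric_change_gradient(params, lo, hi)
  }

  out <- list(estimate = est, midpoint = m_deg, width = width)
  if (!is.null(vcov)) {
    g <- stats::setNames(numeric(nrow(vcov)), rownames(vcov))
    g[names(grad)] <- grad
    se <- sqrt(drop(t(g) %*% vcov %*% g))
    out$se <- se
    out$ci95 <- c(est - 1.96 * se, est + 1.96 * se)
  }
  out
}

strip_foveal <- function(params) {
  if (is.null(params$beta_f)) return(params)
  p <- params; p$beta_f <- NULL
  class(p) <- "segmented_params"
  p
}

# central-difference gradient of mean(hi) - mean(lo) wrt (b1, b2, b3, knot)
numeric_change_gradient <- function(params, lo, hi, h = 1e-6) {
  f <- function(p) {
    sensitivity_mean(hi, 0, strip_foveal(p)) - sensitivity_mean(lo, 0, strip_foveal(p))
  }
  vapply(c("b1", "b2", "b3", "knot"), function(nm) {
    p1 <- params; p2 <- params
    p1[[nm]] <- p1[[nm]] + h
    p2[[nm]] <- p2[[nm]] - h
    class(p1) <- class(p2) <- "segmented_params"
    (f(p1) - f(p2)) / (2 * h)
  }, numeric(1))
}

#' Exact marginal negative log-likelihood of the segmented mixed model
#'
#' Gaussian marginal likelihood of the random-intercept model: within a
#' cluster of size `n` the covariance is `sigma_e^2 I + sigma_u^2 J`
#' (compound symmetry). Each cluster is evaluated with the rank-one
#' determinant and inverse identities (no dense covariance is formed):
#' `det = sigma_e^(2(n-1)) (sigma_e^2 + n sigma_u^2)` and
#' `r' Sigma^-1 r = (sum r^2 - w (sum r)^2) / sigma_e^2` with
#' `w = sigma_u^2 / (sigma_e^2 + n sigma_u^2)`.
#'
#' @param params A [segmented_params()].
#' @param annotated Annotated data frame (see [annotate_dataset()]) with
#'   `sensitivity_db`, `ga_distance_deg`, `visit_month`, `participant_id`
#'   (and `foveal_distance_deg` when the foveal term is enabled).
#' @param drop_intralesional Drop rows with `inside_ga = TRUE` before
#'   evaluating (default; the model describes extralesional loci).
#' @return The negative marginal log-likelihood (scalar).
#' @export
marginal_negloglik <- function(params, annotated, drop_intralesional = TRUE) {
  stopifnot(inherits(params, "segmented_params"), is.data.frame(annotated))
  dat <- model_frame(annotated, drop_intralesional,
                     foveal = !is.null(params$beta_f))
  mu <- sensitivity_mean(dat$d, dat$t, params, foveal_deg = dat$f)
  nll_compound_symmetry(dat$y - mu, dat$cluster, params$sigma_u, params$sigma_e)
}

# shared extraction/validation of the modeling columns
model_frame <- function(annotated, drop_intralesional, foveal) {
  need <- c("sensitivity_db", "ga_distance_deg", "visit_month", "participant_id")
  if (foveal) need <- c(need, "foveal_distance_deg")
  miss <- setdiff(need, names(annotated))
  if (length(miss)) stop("annotated data missing columns: ", paste(miss, collapse = ", "))
  if (drop_intralesional && "inside_ga" %in% names(annotated))
    annotated <- annotated[!annotated$inside_ga, , drop = FALSE]
  if (nrow(annotated) == 0L) stop("no extralesional observations to model")
  cl <- factor(mask_key(annotated$participant_id, annotated$visit_month))
  list(y = as.numeric(annotated$sensitivity_db),
       d = as.numeric(annotated$ga_distance_deg),
       t = as.numeric(annotated$visit_month),
       f = if (foveal) as.numeric(annotated$foveal_distance_deg) else NULL,
       cluster = cl)
}

nll_compound_symmetry <- function(resid, cluster, sigma_u, sigma_e) {
  if (!all(is.finite(resid)) || !is.finite(sigma_u) || !is.finite(sigma_e) ||
      sigma_e <= 0 || sigma_u < 0) return(Inf)
  n_i <- as.vector(rowsum(rep(1, length(resid)), cluster))
  s1 <- as.vector(rowsum(resid, cluster))
  s2 <- as.vector(rowsum(resid^2, cluster))
  a <- sigma_e^2
  denom <- a + n_i * sigma_u^2
  0.5 * sum(n_i * log(2 * pi) + (n_i - 1) * log(a) + log(denom) +
              (s2 - (sigma_u^2 / denom) * s1^2) / a)
}
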