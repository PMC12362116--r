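#' Locally weighted sensitivity-versus-distance smoothing
#'
#' Nearest-neighbor local polynomial regression (LOESS) with the variant
#' fixed for reproducibility: window of the `ceiling(span * n)` nearest
#' points, tricube weights on distances scaled by the window radius, local
#' degree-1 (or user-set) polynomial, no robustness iterations, evaluated on
#' an equally spaced grid inside the observed x-range (no extrapolation).
#'
#' @param x,y Numeric vectors (distance in degrees, sensitivity in dB).
#' @param span Fraction of points in each local window, in `(0, 1]`
#'   (default 0.5, the smoothing parameter used throughout the package).
#' @param degree Local polynomial degree (default 1).
#' @param eval_x Evaluation points; default `n_grid` equally spaced points
#'   spanning `range(x)`.
#' @param n_grid Size of the default evaluation grid.
#' @param stratum Optional label stored on the curve.
#' @return An object of class `smooth_curve`: data frame with `grid_x`,
#'   `fitted_y`, and attributes `span`, `degree`, `stratum`.
#' @examples
#' set.seed(1)
#' x <- runif(60, 0, 8)
#' cv <- loess_fit(x, 5 + 0.5 * x + rnorm(60, 0, 0.5))
#' head(cv)
#' @export
loess_fit <- function(x, y, span = 0.5, degree = 1, eval_x = NULL,
                      n_grid = 200, stratum = "all") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (n < degree + 2)
    stop(errorCondition("too few points for local regression",
                        class = c("perisense_insufficient_data_error",
                                  "error", "condition")))
  q <- ceiling(span * n)
  if (q < degree + 1)
    stop(errorCondition("window smaller than the local polynomial order",
                        class = c("perisense_insufficient_data_error",
                                  "error", "condition")))
  # stable ordering so ties in x resolve identically across input shufflings
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  if (is.null(eval_x))
    eval_x <- seq(min(x), max(x), length.out = n_grid)
  fitted <- vapply(eval_x, function(x0) local_poly(x, y, x0, q, degree),
                   numeric(1))
  out <- data.frame(grid_x = eval_x, fitted_y = fitted)
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  attr(out, "stratum") <- stratum
  class(out) <- c("smooth_curve", "data.frame")
  out
}

# weighted polynomial fit at one evaluation point
local_poly <- function(x, y, x0, q, degree) {
  d <- abs(x - x0)
  h <- sort(d, partial = q)[q]
  if (h == 0) { # at least q points coincide with x0
    return(mean(y[d == 0]))
  }
  use <- d <= h
  w <- (1 - pmin(d[use] / h, 1)^3)^3
  xc <- x[use] - x0
  X <- stats::poly(xc, degree = degree, raw = TRUE)
  X <- cbind(1, matrix(X, ncol = degree))
  keep <- w > 0
  fit <- stats::lm.wfit(X[keep, , drop = FALSE], y[use][keep], w[keep])
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf[1] # value at x0 (basis centered there)
}

#' Smoothed curves by stratum
#'
#' Produces sensitivity-versus-GA-distance curves from annotated data:
#' overall, per testing axis, or per visit month. Intralesional points are
#' excluded; strata with fewer than `min_points` extralesional points are
#' skipped with a message (their labels are returned in the `skipped`
#' attribute), mirroring the practice of not drawing curves for sparse late
#' visits.
#'
#' @param annotated Data frame from [annotate_dataset()].
#' @param stratify_by `"none"`, `"axis"`, or `"visit"`.
#' @param span,degree,n_grid Passed to [loess_fit()].
#' @param min_points Minimum extralesional points per stratum (default 10).
#' @return Data frame with columns `stratum`, `x_deg`, `fitted_db`;
#'   attribute `skipped` lists strata below the minimum.
#' @export
curves_by_stratum <- function(annotated, stratify_by = c("none", "axis", "visit"),
                              span = 0.5, degree = 1, n_grid = 200,
                              min_points = 10) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(is.data.frame(annotated),
            all(c("ga_distance_deg", "sensitivity_db") %in% names(annotated)))
  if ("inside_ga" %in% names(annotated))
    annotated <- annotated[!annotated$inside_ga, , drop = FALSE]
  strata <- switch(stratify_by,
                   none = rep("all", nrow(annotated)),
                   axis = as.character(annotated$axis),
                   visit = sprintf("month_%g", annotated$visit_month))
  out <- list(); skipped <- character()
  for (s in unique(strata)) {
    rows <- strata == s
    if (sum(rows) < max(min_points, degree + 2)) {
      message("skipping stratum '", s, "': only ", sum(rows), " points")
      skipped <- c(skipped, s)
      next
    }
    cv <- loess_fit(annotated$ga_distance_deg[rows],
                    annotated$sensitivity_db[rows],
                    span = span, degree = degree, n_grid = n_grid, stratum = s)
    out[[s]] <- data.frame(stratum = s, x_deg = cv$grid_x,
                           fitted_db = cv$fitted_y, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stratum = character(), x_deg = numeric(), fitted_db = numeric())
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "span") <- span
  attr(res, "degree") <- degree
  res
}

#' Write smoothed curves to CSV
#'
#' @param curves Data frame from [curves_by_stratum()].
#' @param path Output path.
#' @export
write_curves_csv <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot smoothed sensitivity-versus-distance curves
#'
#' Simple base-graphics rendering of the output of [curves_by_stratum()],
#' one line per stratum.
#'
#' @param curves Data frame from [curves_by_stratum()].
#' @param ... Passed to [graphics::matplot()]-style plotting.
#' @export
plot_curves <- function(curves, ...) {
  strata <- unique(curves$stratum)
  cols <- grDevices::hcl.colors(max(length(strata), 2), "Dark 3")
  plot(NA, xlim = range(curves$x_deg), ylim = range(curves$fitted_db),
       xlab = "GA distance (degrees)", ylab = "sensitivity (dB)", ...)
  for (i in seq_along(strata)) {
    rows <- curves$stratum == strata[i]
    graphics::lines(curves$x_deg[rows], curves$fitted_db[rows], col = cols[i])
  }
  graphics::legend("bottomright", legend = strata, col = cols[seq_along(strata)],
                   lty = 1, cex = 0.8, bty = "n")
  invisible(curves)
}
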