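# Independent oracles, deliberately written by the most direct route so they
# share no code with the package implementations they check.

# exhaustive nearest-GA-pixel search over every GA pixel center
oracle_distance <- function(locus, mask) {
  ga <- which(mask$pixels, arr.ind = TRUE)
  gx <- ga[, "col"] - 1
  gy <- ga[, "row"] - 1
  vapply(seq_len(nrow(locus)), function(i) {
    px <- mask$fovea_px[["x"]] + locus$x_deg[i] / mask$deg_per_pixel
    py <- mask$fovea_px[["y"]] - locus$y_deg[i] / mask$deg_per_pixel
    cx <- min(max(round(px), 0), ncol(mask$pixels) - 1)
    cy <- min(max(round(py), 0), nrow(mask$pixels) - 1)
    if (mask$pixels[cy + 1, cx + 1]) return(0)
    sqrt(min((gx - px)^2 + (gy - py)^2)) * mask$deg_per_pixel
  }, numeric(1))
}

# dense multivariate-normal negative log-likelihood from explicit per-cluster
# block covariance matrices
oracle_dense_nll <- function(params, annotated) {
  cl <- paste(annotated$participant_id, annotated$visit_month)
  mu <- sensitivity_mean(annotated$ga_distance_deg, annotated$visit_month,
                         params,
                         foveal_deg = if (!is.null(params$beta_f))
                           annotated$foveal_distance_deg)
  r <- annotated$sensitivity_db - mu
  nll <- 0
  for (g in unique(cl)) {
    ri <- r[cl == g]
    n <- length(ri)
    Sigma <- diag(params$sigma_e^2, n) + matrix(params$sigma_u^2, n, n)
    nll <- nll + 0.5 * (n * log(2 * pi) +
                          determinant(Sigma, logarithm = TRUE)$modulus +
                          drop(t(ri) %*% solve(Sigma) %*% ri))
  }
  as.numeric(nll)
}

# per-window weighted least squares via lm(), one regression per grid point
oracle_loess <- function(x, y, eval_x, span = 0.5, degree = 1) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(eval_x, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    sel <- which(d <= h)
    w <- (1 - (d[sel] / h)^3)^3
    df <- data.frame(y = y[sel], x = x[sel])
    fit <- lm(y ~ poly(x, degree, raw = TRUE), data = df, weights = w)
    unname(predict(fit, newdata = data.frame(x = x0)))
  }, numeric(1))
}

# connected components of a binary matrix (4-connectivity), breadth-first
count_components <- function(px) {
  lab <- matrix(0L, nrow(px), ncol(px))
  ncomp <- 0L
  for (start in which(px)) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    nr <- nrow(px)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= ncol(px)) {
          idx <- (nb[2] - 1L) * nr + nb[1]
          if (px[idx] && lab[idx] == 0L) {
            lab[idx] <- ncomp
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  ncomp
}

# random mask with a given number of disc-shaped lesions
random_mask <- function(npx = 64, n_lesions = 2, deg_per_pixel = 0.1) {
  px <- matrix(FALSE, npx, npx)
  for (i in seq_len(n_lesions)) {
    cx <- runif(1, npx * 0.15, npx * 0.85)
    cy <- runif(1, npx * 0.15, npx * 0.85)
    rad <- runif(1, 2, npx / 8)
    xs <- matrix(rep(0:(npx - 1), each = npx), npx)
    ys <- matrix(rep(0:(npx - 1), npx), npx)
    px <- px | ((xs - cx)^2 + (ys - cy)^2 <= rad^2)
  }
  lesion_mask(px, deg_per_pixel = deg_per_pixel, visit_month = 0,
              participant_id = "X")
}

# annotated data straight from the regression model (no rasters), for tests
# of the fitting machinery alone
direct_annotated <- function(n_participants = 10, visit_months = c(0, 6, 12),
                             n_loci = 30, params = segmented_params(),
                             sigma_u = 2, sigma_e = 3, d_max = 10,
                             with_foveal = FALSE) {
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (m in visit_months) {
      u <- rnorm(1, 0, sigma_u)
      d <- runif(n_loci, 0, d_max)
      fov <- runif(n_loci, 0, 12)
      mu <- sensitivity_mean(d, m, params,
                             foveal_deg = if (!is.null(params$beta_f)) fov)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = sprintf("P%02d", p), visit_month = m,
        ga_distance_deg = d, foveal_distance_deg = fov,
        sensitivity_db = mu + u + rnorm(n_loci, 0, sigma_e),
        inside_ga = FALSE)
    }
  }
  do.call(rbind, rows)
}
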