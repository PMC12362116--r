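#' Euclidean distance from test loci to the nearest GA pixel
#'
#' For each locus, returns the shortest straight-line distance (in degrees)
#' from the locus center to the center of the nearest GA pixel of the mask.
#' With multifocal atrophy this is automatically the minimum over all
#' lesions. A locus whose containing pixel is GA is intralesional and gets
#' distance 0.
#'
#' Only morphological boundary pixels (GA pixels with at least one non-GA
#' 4-neighbor) need to be searched for extralesional loci: the nearest GA
#' pixel to an exterior point is always such a pixel.
#'
#' @param locus A `t_grid` data frame (or any data frame with `x_deg`,
#'   `y_deg`), possibly with several rows.
#' @param mask A [lesion_mask()]; must contain at least one GA pixel.
#' @return Numeric vector of distances in degrees, one per locus row.
#' @seealso [annotate_dataset()]
#' @export
distance_to_ga <- function(locus, mask) {
  stopifnot(inherits(mask, "lesion_mask"), is.data.frame(locus),
            all(c("x_deg", "y_deg") %in% names(locus)))
  if (!any(mask$pixels))
    stop(errorCondition("mask contains no GA pixels",
                        class = c("perisense_no_lesion_error", "error", "condition")))
  px <- locus_to_raster(locus, mask)
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  out_of_field <- px$x < -0.5 | px$x > nc - 0.5 | px$y < -0.5 | px$y > nr - 0.5
  if (any(out_of_field))
    stop(errorCondition(
      sprintf("%d locus/loci fall outside the imaging field", sum(out_of_field)),
      class = c("perisense_out_of_field_error", "error", "condition")))

  # containing pixel (nearest center), clamped to the raster
  cx <- pmin(pmax(round(px$x), 0), nc - 1)
  cy <- pmin(pmax(round(px$y), 0), nr - 1)
  inside <- mask$pixels[cbind(cy + 1, cx + 1)]

  d <- numeric(nrow(locus))
  if (any(!inside)) {
    bd <- ga_boundary_px(mask$pixels) # columns x, y (0-based)
    for (i in which(!inside)) {
      d[i] <- sqrt(min((bd[, 1] - px$x[i])^2 + (bd[, 2] - px$y[i])^2))
    }
    d <- d * mask$deg_per_pixel
  }
  d
}

# 0-based raster coordinates of loci; image rows grow downward so +y_deg
# (superior) maps to smaller row indices.
locus_to_raster <- function(locus, mask) {
  list(x = mask$fovea_px[["x"]] + locus$x_deg / mask$deg_per_pixel,
       y = mask$fovea_px[["y"]] - locus$y_deg / mask$deg_per_pixel)
}

# boundary GA pixels as a 2-column matrix of 0-based (x, y); a GA pixel is
# boundary if any 4-neighbor is background or it touches the raster edge
ga_boundary_px <- function(pixels) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  interior <- pixels
  pad <- function(shift_r, shift_c) {
    m <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + shift_r; cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    m[ok_r, ok_c] <- pixels[rs[ok_r], cs[ok_c]]
    m
  }
  all_nb_ga <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  boundary <- pixels & !all_nb_ga
  idx <- which(boundary, arr.ind = TRUE)
  cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
}

#' Annotate sensitivity records with GA and foveal distances
#'
#' Joins each sensitivity record with the lesion mask of its own visit
#' (distances are recomputed at every time point so that lesion growth is
#' reflected) and with the grid geometry. Each output row carries the GA
#' distance in degrees (0 for intralesional loci), an `inside_ga` flag, and
#' the Euclidean distance from the locus to the foveal center.
#'
#' @param records Data frame of sensitivity records with columns
#'   `participant_id`, `visit_month`, `locus_id`, `sensitivity_db`,
#'   `scotoma` (and optionally `axis`).
#' @param masks List of [lesion_mask()] objects; exactly one per
#'   (participant, visit) present in `records`.
#' @param grid A `t_grid` from [build_t_grid()].
#' @return Data frame of annotated points: the record columns plus `axis`,
#'   `axis_orientation`, `ga_distance_deg`, `inside_ga`,
#'   `foveal_distance_deg`.
#' @export
annotate_dataset <- function(records, masks, grid) {
  stopifnot(is.data.frame(records), is.list(masks), is.data.frame(grid))
  need <- c("participant_id", "visit_month", "locus_id", "sensitivity_db", "scotoma")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records is missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$locus_id %in% grid$locus_id))
    stop("records contain locus_id values absent from the grid")

  keys <- vapply(masks, function(m) mask_key(m$participant_id, m$visit_month), "")
  if (anyDuplicated(keys)) stop("multiple masks supplied for the same (participant, visit)")
  names(masks) <- keys

  rec_key <- mask_key(records$participant_id, records$visit_month)
  missing_keys <- setdiff(unique(rec_key), keys)
  if (length(missing_keys))
    stop(errorCondition(
      paste0("missing lesion mask for (participant, visit): ",
             paste(missing_keys, collapse = ", ")),
      class = c("perisense_missing_mask_error", "error", "condition")))

  gi <- match(records$locus_id, grid$locus_id)
  out <- records
  out$axis <- grid$axis[gi]
  out$axis_orientation <- axis_orientation(out$axis)
  out$foveal_distance_deg <- sqrt(grid$x_deg[gi]^2 + grid$y_deg[gi]^2)
  out$ga_distance_deg <- NA_real_
  out$inside_ga <- NA

  for (k in unique(rec_key)) {
    rows <- which(rec_key == k)
    m <- masks[[k]]
    loc <- grid[match(records$locus_id[rows], grid$locus_id), ]
    d <- distance_to_ga(loc, m)
    out$ga_distance_deg[rows] <- d
    out$inside_ga[rows] <- d == 0 & is_inside_ga(loc, m)
  }
  # intralesional loci get exact distance 0 by convention
  out$ga_distance_deg[out$inside_ga] <- 0
  rownames(out) <- NULL
  out
}

# TRUE when the pixel containing the locus is GA
is_inside_ga <- function(locus, mask) {
  px <- locus_to_raster(locus, mask)
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  cx <- pmin(pmax(round(px$x), 0), nc - 1)
  cy <- pmin(pmax(round(px$y), 0), nr - 1)
  mask$pixels[cbind(cy + 1, cx + 1)]
}

#' Write annotated points to CSV
#'
#' @param annotated Data frame from [annotate_dataset()].
#' @param path Output path.
#' @export
write_annotated_csv <- function(annotated, path) {
  utils::write.csv(annotated, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
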