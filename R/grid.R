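#' Build the T-shaped microperimetry testing grid
#'
#' Constructs the fovea-centered T-shaped pattern of test loci: one central
#' locus at the fovea plus three arms of evenly spaced loci extending
#' temporally (+x), superiorly (+y) and inferiorly (-y). The defaults (15
#' degrees temporal, 12 superior, 12 inferior, 1 degree spacing) give the
#' 40-locus pattern used for perilesional sensitivity mapping. Coordinates
#' follow a right-eye convention (temporal = +x); mirror `x_deg` at data
#' ingest for left eyes.
#'
#' Locus IDs are assigned deterministically: 0 for the center, then the
#' temporal, superior and inferior arms in increasing offset.
#'
#' @param temporal_deg,superior_deg,inferior_deg Arm lengths in degrees
#'   (>= 0); each must be an exact multiple of `spacing_deg`.
#' @param spacing_deg Spacing between adjacent locus centers in degrees (> 0).
#'
#' @return A data frame of class `t_grid` with columns `locus_id`, `axis`
#'   (one of `"center"`, `"temporal"`, `"superior"`, `"inferior"`),
#'   `offset_deg` (distance from the fovea along the axis), `x_deg`, `y_deg`.
#' @examples
#' g <- build_t_grid()
#' nrow(g) # 40
#' @export
build_t_grid <- function(temporal_deg = 15, superior_deg = 12,
                         inferior_deg = 12, spacing_deg = 1) {
  stopifnot(is.numeric(temporal_deg), is.numeric(superior_deg),
            is.numeric(inferior_deg), is.numeric(spacing_deg))
  if (spacing_deg <= 0) stop("invalid geometry: spacing_deg must be > 0")
  arms <- c(temporal = temporal_deg, superior = superior_deg,
            inferior = inferior_deg)
  if (any(arms < 0)) stop("invalid geometry: arm lengths must be >= 0")
  n_arm <- arms / spacing_deg
  if (any(abs(n_arm - round(n_arm)) > 1e-8))
    stop("invalid geometry: each arm length must be an exact multiple of spacing_deg")
  n_arm <- stats::setNames(as.integer(round(n_arm)), names(arms))

  offs <- function(n) if (n > 0) seq_len(n) * spacing_deg else numeric(0)
  t_off <- offs(n_arm[["temporal"]])
  s_off <- offs(n_arm[["superior"]])
  i_off <- offs(n_arm[["inferior"]])

  g <- data.frame(
    locus_id = seq_len(1L + length(t_off) + length(s_off) + length(i_off)) - 1L,
    axis = c("center", rep("temporal", length(t_off)),
             rep("superior", length(s_off)), rep("inferior", length(i_off))),
    offset_deg = c(0, t_off, s_off, i_off),
    x_deg = c(0, t_off, rep(0, length(s_off)), rep(0, length(i_off))),
    y_deg = c(0, rep(0, length(t_off)), s_off, -i_off),
    stringsAsFactors = FALSE
  )
  class(g) <- c("t_grid", "data.frame")
  g
}

#' Orientation of a grid axis
#'
#' Temporal loci (and the central locus) lie on the horizontal meridian;
#' superior and inferior loci on the vertical meridian. Used as a nesting
#' level when simulating and reporting hierarchical data.
#'
#' @param axis Character vector of axis labels.
#' @return `"horizontal"` or `"vertical"` for each element.
#' @export
axis_orientation <- function(axis) {
  ifelse(axis %in% c("superior", "inferior"), "vertical", "horizontal")
}

#' Read and write testing grids as CSV
#'
#' @param grid A `t_grid` data frame.
#' @param path File path.
#' @return `read_grid_csv` returns a `t_grid` data frame.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(is.data.frame(grid),
            all(c("locus_id", "axis", "offset_deg", "x_deg", "y_deg") %in% names(grid)))
  utils::write.csv(as.data.frame(grid)[, c("locus_id", "axis", "offset_deg",
                                           "x_deg", "y_deg")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "axis", "offset_deg", "x_deg", "y_deg")
  if (!all(need %in% names(g)))
    stop("grid CSV must have columns: ", paste(need, collapse = ", "))
  g <- g[need]
  class(g) <- c("t_grid", "data.frame")
  g
}
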