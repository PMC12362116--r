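#' Physical unit scale for mesopic microperimetry
#'
#' Bundles the constants that relate the instrument's decibel attenuation
#' scale to stimulus luminance, and degrees of visual angle to retinal
#' distance in micrometers. Sensitivity in dB is attenuation relative to the
#' maximum stimulus luminance: 0 dB is the brightest (dimmest percept,
#' poorest sensitivity) and the top of `db_range` the dimmest stimulus the
#' device can present.
#'
#' @param um_per_deg Micrometers of retinal distance per degree of visual
#'   angle. The default 290 is a standard macular conversion (2 degrees is
#'   approximately 580 micrometers).
#' @param max_luminance_cdm2 Luminance of the 0 dB (maximum) stimulus in
#'   cd/m^2; default 127, the mesopic maximum of the MP-1 class of devices.
#' @param db_range Length-2 numeric, the attainable sensitivity range in dB;
#'   default `c(0, 20)`.
#'
#' @return An object of class `unit_scale`.
#' @examples
#' sc <- unit_scale()
#' db_to_luminance(10, sc) # 12.7 cd/m^2
#' deg_to_um(2, sc)        # 580 um
#' @export
unit_scale <- function(um_per_deg = 290, max_luminance_cdm2 = 127,
                       db_range = c(0, 20)) {
  stopifnot(is.numeric(um_per_deg), length(um_per_deg) == 1L,
            is.numeric(max_luminance_cdm2), length(max_luminance_cdm2) == 1L,
            is.numeric(db_range), length(db_range) == 2L)
  if (um_per_deg <= 0) stop("um_per_deg must be > 0")
  if (max_luminance_cdm2 <= 0) stop("max_luminance_cdm2 must be > 0")
  if (db_range[1] >= db_range[2]) stop("db_range lower bound must be below upper bound")
  structure(list(um_per_deg = um_per_deg,
                 max_luminance_cdm2 = max_luminance_cdm2,
                 db_range = db_range),
            class = "unit_scale")
}

#' @export
print.unit_scale <- function(x, ...) {
  cat(sprintf("unit_scale: %g um/deg, max %g cd/m^2, dB range [%g, %g]\n",
              x$um_per_deg, x$max_luminance_cdm2, x$db_range[1], x$db_range[2]))
  invisible(x)
}

#' Convert sensitivity in dB to stimulus luminance
#'
#' A sensitivity of `db` means the participant saw a stimulus attenuated by
#' `db` decibels relative to the maximum luminance, i.e.
#' `max_luminance * 10^(-db/10)` cd/m^2.
#'
#' @param db Numeric vector of sensitivities in dB, inside the scale's range.
#' @param scale A [unit_scale()].
#' @return Luminance in cd/m^2.
#' @export
db_to_luminance <- function(db, scale = unit_scale()) {
  stopifnot(inherits(scale, "unit_scale"), is.numeric(db))
  if (any(db < scale$db_range[1] - 1e-12 | db > scale$db_range[2] + 1e-12, na.rm = TRUE))
    stop(sprintf("dB values outside the attainable range [%g, %g]",
                 scale$db_range[1], scale$db_range[2]))
  scale$max_luminance_cdm2 * 10^(-db / 10)
}

#' Convert degrees of visual angle to retinal micrometers (and back)
#'
#' @param deg,um Non-negative numeric vectors.
#' @param scale A [unit_scale()].
#' @return `deg_to_um` returns micrometers; `um_to_deg` is its exact inverse.
#' @export
deg_to_um <- function(deg, scale = unit_scale()) {
  stopifnot(inherits(scale, "unit_scale"), is.numeric(deg))
  if (any(deg < 0, na.rm = TRUE)) stop("deg must be non-negative")
  deg * scale$um_per_deg
}

#' @rdname deg_to_um
#' @export
um_to_deg <- function(um, scale = unit_scale()) {
  stopifnot(inherits(scale, "unit_scale"), is.numeric(um))
  if (any(um < 0, na.rm = TRUE)) stop("um must be non-negative")
  um / scale$um_per_deg
}
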