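#' Binary geographic-atrophy lesion mask
#'
#' Represents the reading-center annotation of GA at one visit as a binary
#' raster registered to the microperimetry frame: `TRUE` pixels are GA.
#' Rows follow image convention (y increases downward), so a locus at
#' `y_deg > 0` (superior retina) maps to rows above the fovea row. Pixel
#' indices are 0-based with pixel centers on integer coordinates; the fovea
#' sits at `fovea_px` (default: raster center).
#'
#' @param pixels Logical (or 0/1) matrix, `TRUE` = GA.
#' @param deg_per_pixel Degrees of visual angle per pixel; default `30/768`,
#'   a 30-degree field captured at 768 x 768.
#' @param fovea_px Numeric `c(x, y)` raster coordinates (0-based) of the
#'   fovea; default the raster center.
#' @param visit_month Months since baseline for this annotation.
#' @param participant_id Identifier used to key masks to sensitivity records.
#'
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels, deg_per_pixel = 30 / 768, fovea_px = NULL,
                        visit_month = 0, participant_id = NA_character_) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop("pixels must not contain NA")
  if (!is.numeric(deg_per_pixel) || length(deg_per_pixel) != 1L || deg_per_pixel <= 0)
    stop("deg_per_pixel must be a single positive number")
  if (is.null(fovea_px))
    fovea_px <- c(x = (ncol(pixels) - 1) / 2, y = (nrow(pixels) - 1) / 2)
  fovea_px <- stats::setNames(as.numeric(fovea_px), c("x", "y"))
  if (fovea_px["x"] < 0 || fovea_px["x"] > ncol(pixels) - 1 ||
      fovea_px["y"] < 0 || fovea_px["y"] > nrow(pixels) - 1)
    stop("fovea_px must lie inside the raster bounds")
  structure(list(pixels = pixels, deg_per_pixel = deg_per_pixel,
                 fovea_px = fovea_px, visit_month = as.numeric(visit_month),
                 participant_id = as.character(participant_id)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion_mask: %dx%d px (%.4f deg/px), %d GA px, participant %s, month %g\n",
              nrow(x$pixels), ncol(x$pixels), x$deg_per_pixel,
              sum(x$pixels), x$participant_id, x$visit_month))
  invisible(x)
}

mask_key <- function(participant_id, visit_month) {
  sprintf("%s@m%g", participant_id, visit_month)
}

#' Area of a lesion mask
#'
#' @param mask A [lesion_mask()].
#' @param units `"deg2"` (square degrees) or `"px"`.
#' @return Total GA area.
#' @export
mask_area <- function(mask, units = c("deg2", "px")) {
  stopifnot(inherits(mask, "lesion_mask"))
  units <- match.arg(units)
  n <- sum(mask$pixels)
  if (units == "px") n else n * mask$deg_per_pixel^2
}

#' Read and write lesion masks
#'
#' Masks are written as single-channel PNG (0 = background, 255 = GA) or, for
#' plain-text fixtures, as whitespace-separated 0/1 matrices (`.txt`). A JSON
#' sidecar next to the raster stores `deg_per_pixel`, `fovea_px`,
#' `visit_month` and `participant_id`.
#'
#' @param mask A [lesion_mask()].
#' @param path Raster path ending in `.png` or `.txt`; the sidecar replaces
#'   that extension with `.json`.
#' @return `read_mask` returns a [lesion_mask()]; `write_mask` the path,
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(ifelse(mask$pixels, 1, 0), target = path)
  } else if (ext == "txt") {
    utils::write.table(ifelse(mask$pixels, 1L, 0L), path,
                       row.names = FALSE, col.names = FALSE)
  } else stop("unsupported mask extension: ", ext)
  side <- list(deg_per_pixel = mask$deg_per_pixel,
               fovea_px = as.list(mask$fovea_px),
               visit_month = mask$visit_month,
               participant_id = mask$participant_id)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    px <- img > 0.5
  } else if (ext == "txt") {
    px <- as.matrix(utils::read.table(path)) > 0
    dimnames(px) <- NULL
  } else stop("unsupported mask extension: ", ext)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  lesion_mask(px, deg_per_pixel = side$deg_per_pixel,
              fovea_px = unlist(side$fovea_px),
              visit_month = side$visit_month,
              participant_id = side$participant_id)
}

sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", ".json", path)
}
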