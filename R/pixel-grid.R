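#' Attach a physical pixel size to an intensity or label matrix
#'
#' A `pixel_grid` is an ordinary numeric matrix carrying a `pixel_size`
#' attribute (micrometres per pixel). All physical thresholds in the pipeline
#' (minimum colonoid area, slice width, structuring-element radii) are
#' converted through this scale and never hard-coded in pixels.
#'
#' @param values numeric matrix of non-negative intensities (or integer labels).
#' @param pixel_size physical pixel size, um/px; must be > 0.
#' @return the matrix with class `pixel_grid` and a `pixel_size` attribute.
#' @export
pixel_grid <- function(values, pixel_size = 1) {
  stopifnot(is.matrix(values), is.numeric(pixel_size), length(pixel_size) == 1,
            is.finite(pixel_size), pixel_size > 0)
  if (any(!is.finite(values))) stop("pixel_grid values must be finite")
  attr(values, "pixel_size") <- pixel_size
  class(values) <- c("pixel_grid", class(values))
  values
}

#' Physical pixel size of an image
#'
#' @param img matrix, possibly with a `pixel_size` attribute.
#' @param default value used when the attribute is absent.
#' @return pixel size in um/px.
#' @export
px_size <- function(img, default = 1) {
  ps <- attr(img, "pixel_size")
  if (is.null(ps)) default else ps
}

# strip class but keep data; internal ops work on plain matrices
as_plain <- function(img) {
  attributes(img) <- list(dim = dim(img))
  img
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), px_size(x), min(x), max(x)))
  invisible(x)
}

# physical centre coordinates (um, y up) of every TRUE pixel in a mask
mask_coords_um <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 0.5) * pixel_size,
        y = (nrow(mask) - idx[, 1] + 0.5) * pixel_size)
}

norm_angle <- function(deg) ((deg %% 360) + 360) %% 360

#' Rotate an image about a point with nearest-neighbour interpolation
#'
#' Content is rotated counter-clockwise (in the package's y-up convention) by
#' `theta_deg` about `center`; pixels mapping outside the source are set to
#' `fill`. Nearest-neighbour sampling preserves intensity values exactly, which
#' matters for ratio images.
#'
#' @param img numeric matrix.
#' @param theta_deg rotation angle, degrees CCW.
#' @param center `c(row, col)` rotation centre in (possibly fractional) pixel
#'   units; default is the matrix centre.
#' @param fill value for unmapped output pixels.
#' @return matrix of the same dimensions.
#' @export
rotate_nn <- function(img, theta_deg, center = (dim(img) + 1) / 2, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  u <- cc - center[2]
  v <- -(rr - center[1])           # y up
  us <- ct * u + st * v            # inverse map: source = R(-theta) %*% p
  vs <- -st * u + ct * v
  cs <- round(center[2] + us)
  rs <- round(center[1] - vs)
  out <- matrix(fill, nr, nc)
  ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
  out[ok] <- img[cbind(rs[ok], cs[ok])]
  out
}

#' Feret extent of a mask along a direction
#'
#' Length of the mask's projection onto a direction, measured between extreme
#' pixel centres plus one pixel footprint, so a solid axis-aligned rectangle of
#' N columns has extent exactly N pixels along the x axis.
#'
#' @param mask logical matrix.
#' @param angle_deg direction, degrees CCW from +x.
#' @param pixel_size um/px.
#' @return extent in micrometres.
#' @export
feret_extent <- function(mask, angle_deg, pixel_size = px_size(mask)) {
  stopifnot(any(mask))
  xy <- mask_coords_um(mask, pixel_size)
  a <- angle_deg * pi / 180
  p <- xy[, 1] * cos(a) + xy[, 2] * sin(a)
  diff(range(p)) + pixel_size
}

# geometric centroid (um, y-up coords) of a mask
mask_centroid_um <- function(mask, pixel_size) {
  xy <- mask_coords_um(mask, pixel_size)
  colMeans(xy)
}

# intensity-weighted centroid (um) of img restricted to mask
weighted_centroid_um <- function(img, mask, pixel_size) {
  xy <- mask_coords_um(mask, pixel_size)
  w <- img[mask]
  if (sum(w) <= 0) return(c(x = NA_real_, y = NA_real_))
  c(x = sum(xy[, 1] * w) / sum(w), y = sum(xy[, 2] * w) / sum(w))
}
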