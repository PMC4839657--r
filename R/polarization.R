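#' Polarization vector
#'
#' Direction and strength of a colonoid's spatial marker asymmetry. The
#' `sox9_slope` metric carries the ratio-gradient magnitude in normalized
#' ratio units per um; the `edu_centroid` metric carries the centroid offset
#' as a fraction of the colonoid length along the offset direction (at most
#' 0.5 on symmetric masks).
#'
#' @param angle_deg direction, degrees CCW from the sink-to-source axis, in
#'   `[0, 360)`; may be NA when undefined (zero magnitude).
#' @param magnitude non-negative metric value.
#' @param metric `"sox9_slope"` or `"edu_centroid"`.
#' @return a `polarization_vector` list.
#' @export
polarization_vector <- function(angle_deg, magnitude,
                                metric = c("sox9_slope", "edu_centroid")) {
  metric <- match.arg(metric)
  stopifnot(magnitude >= 0)
  if (!is.na(angle_deg)) angle_deg <- norm_angle(angle_deg)
  structure(list(angle_deg = angle_deg, magnitude = magnitude,
                 metric = metric), class = "polarization_vector")
}

#' @export
print.polarization_vector <- function(x, ...) {
  cat(sprintf("<polarization_vector %s> angle %.1f deg, magnitude %.4g\n",
              x$metric, x$angle_deg, x$magnitude))
  invisible(x)
}

#' Per-pixel ratio image inside a mask
#'
#' Divides numerator by denominator pixelwise inside the mask, normalizing a
#' marker by a cell-number proxy (EGFP/DsRed or EdU/Hoechst). Denominator
#' pixels below a floor (a fraction of the in-mask median denominator) are
#' set to 0 and excluded from downstream slices via the `"valid"` attribute.
#'
#' @param num,den co-registered intensity matrices.
#' @param mask logical matrix.
#' @param floor_frac denominator floor as a fraction of its in-mask median.
#' @return ratio matrix (0 outside mask and at floored pixels) with
#'   attributes `"valid"` (logical matrix) and `"n_excluded"`.
#' @export
ratio_image <- function(num, den, mask, floor_frac = 0.01) {
  stopifnot(all(dim(num) == dim(den)), all(dim(num) == dim(mask)), any(mask))
  med <- median(den[mask])
  if (med <= 0 && all(den[mask] <= 0))
    stop("denominator is zero everywhere inside the mask")
  floor_v <- floor_frac * med
  valid <- mask & den > floor_v
  n_excl <- sum(mask) - sum(valid)
  if (n_excl > 0)
    message(n_excl, " pixel(s) excluded by the denominator floor")
  out <- matrix(0, nrow(num), ncol(num))
  out[valid] <- num[valid] / den[valid]
  structure(out, valid = valid, n_excluded = n_excl,
            pixel_size = px_size(num))
}

#' Mean-intensity profile of a horizontal slice through an object's centre
#'
#' Averages intensity per column over a horizontal band of physical width
#' `slice_width_um` centred on the object's bounding-box centre, restricted
#' to mask pixels. Columns whose band contains no mask pixel are omitted.
#'
#' @param img intensity matrix.
#' @param mask logical matrix (non-empty).
#' @param slice_width_um band width, um.
#' @param pixel_size um/px.
#' @return data.frame with columns `x_um` (column centre positions) and
#'   `intensity`.
#' @export
center_slice_profile <- function(img, mask, slice_width_um = 20,
                                 pixel_size = px_size(img)) {
  stopifnot(any(mask))
  rows_in <- which(rowSums(mask) > 0)
  c_row <- (min(rows_in) + max(rows_in)) / 2
  w_px <- max(1L, round(slice_width_um / pixel_size))
  start <- floor(c_row - w_px / 2) + 1L
  band <- max(1L, start):min(nrow(img), start + w_px - 1L)
  m <- mask[band, , drop = FALSE]
  s <- colSums(img[band, , drop = FALSE] * m)
  n <- colSums(m)
  keep <- which(n > 0)
  data.frame(x_um = (keep - 0.5) * pixel_size, intensity = s[keep] / n[keep],
             n_px = n[keep])
}

# least-squares slope of y on x, optionally weighted (inverse-variance for
# column means: weight = number of averaged pixels); NA when degenerate
ls_slope <- function(x, y, w = rep(1, length(x))) {
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  vx <- sum(w * (x - xb)^2)
  if (vx == 0) return(NA_real_)
  sum(w * (x - xb) * (y - yb)) / vx
}

#' Rotation-slope (Sox9EGFP) polarization of one colonoid
#'
#' The normalized-ratio image is rotated in 1-degree steps through 180
#' degrees about the centroid of the object's bounding box using
#' nearest-neighbour interpolation; at each rotation the mean intensity of a
#' 20-um horizontal slice through the centre is fit with a least-squares
#' line. The rotation producing the largest absolute slope gives the
#' polarization direction (from the rotation angle and the slope sign) and
#' its absolute slope, in ratio units per um, gives the magnitude. Ties in
#' absolute slope resolve to the smaller rotation angle.
#'
#' @param ratio_img ratio matrix, typically from [ratio_image()] (its
#'   `"valid"` attribute, when present, excludes floored pixels from slices).
#' @param mask logical object mask; area must be at least `min_area_um2`.
#' @param pixel_size um/px.
#' @param slice_width_um slice width, um.
#' @param min_area_um2 minimum object area, um^2.
#' @return a [polarization_vector()] with metric `"sox9_slope"`; attributes
#'   `"theta_star"` (selected rotation) and `"slope"` (signed slope).
#' @export
sox9_polarization <- function(ratio_img, mask, pixel_size = px_size(ratio_img),
                              slice_width_um = 20, min_area_um2 = 1000) {
  stopifnot(any(mask))
  if (sum(mask) * pixel_size^2 < min_area_um2)
    stop("object below minimum area for the rotation-slope metric")
  valid <- attr(ratio_img, "valid") %||% mask
  idx <- which(mask, arr.ind = TRUE)
  rb <- range(idx[, 1]); cb <- range(idx[, 2])
  # pad the crop so no rotation clips the object
  h <- diff(rb) + 1L; w <- diff(cb) + 1L
  pad <- ceiling((sqrt(h^2 + w^2) - min(h, w)) / 2) + 2L
  nr0 <- nrow(mask); nc0 <- ncol(mask)
  rs <- (rb[1] - pad):(rb[2] + pad); cs <- (cb[1] - pad):(cb[2] + pad)
  take <- function(m, fill = 0) {
    out <- matrix(fill, length(rs), length(cs))
    rok <- rs >= 1 & rs <= nr0; cok <- cs >= 1 & cs <= nc0
    out[rok, cok] <- m[rs[rok], cs[cok]]
    out
  }
  crop_img <- take(as_plain(ratio_img))
  crop_val <- take(valid & mask)
  center <- c(mean(range(which(rowSums(crop_val) > 0))),
              mean(range(which(colSums(crop_val) > 0))))
  slopes <- rep(NA_real_, 180)
  for (theta in 0:179) {
    rimg <- rotate_nn(crop_img, theta, center)
    rval <- rotate_nn(crop_val * 1, theta, center) > 0.5
    if (!any(rval)) next
    prof <- center_slice_profile(rimg, rval, slice_width_um, pixel_size)
    if (nrow(prof) < 3) next
    slopes[theta + 1L] <- ls_slope(prof$x_um, prof$intensity, prof$n_px)
  }
  n_skipped <- sum(is.na(slopes))
  if (n_skipped == 180L) stop("no rotation produced a usable slice profile")
  theta_star <- which.max(abs(slopes)) - 1L      # ties: smaller angle wins
  sl_star <- slopes[theta_star + 1L]
  # sub-degree peak localization: |slope|(theta) is smooth (s*|cos|) near its
  # maximum, so a local quadratic fit over +/-10 degrees refines the 1-degree
  # grid argmax; |slope| is 180-periodic
  off <- -10:10
  yw <- abs(slopes[(theta_star + off) %% 180 + 1L])
  ok <- !is.na(yw)
  dtheta <- 0
  if (sum(ok) >= 5) {
    q <- coef(lm(yw[ok] ~ off[ok] + I(off[ok]^2)))
    if (is.finite(q[3]) && q[3] < 0)
      dtheta <- max(-10, min(10, -q[2] / (2 * q[3])))
  }
  theta_ref <- theta_star + dtheta
  angle <- if (sl_star > 0) norm_angle(-theta_ref)
           else norm_angle(180 - theta_ref)
  v <- polarization_vector(angle, abs(sl_star), "sox9_slope")
  attr(v, "theta_star") <- theta_star
  attr(v, "slope") <- sl_star
  attr(v, "n_skipped") <- n_skipped
  v
}

#' Centroid-offset (EdU) polarization of one colonoid
#'
#' EdU intensity is first divided by Hoechst 33342 pixelwise (cell-number
#' normalization); the vector from the mask's geometric centroid to the
#' normalized EdU intensity-weighted centroid gives the polarization angle,
#' and its length divided by the colonoid's Feret extent along that direction
#' gives the magnitude.
#'
#' @param edu,hoechst co-registered intensity matrices.
#' @param mask logical object mask.
#' @param pixel_size um/px.
#' @param floor_frac Hoechst floor fraction passed to [ratio_image()].
#' @return a [polarization_vector()] with metric `"edu_centroid"`; when the
#'   object carries no EdU signal the magnitude is 0, the angle NA and
#'   attribute `"undefined"` is TRUE.
#' @export
edu_polarization <- function(edu, hoechst, mask, pixel_size = px_size(edu),
                             floor_frac = 0.01) {
  stopifnot(any(mask))
  nrm <- ratio_image(edu, hoechst, mask, floor_frac)
  valid <- attr(nrm, "valid")
  geo <- mask_centroid_um(mask, pixel_size)
  if (sum(nrm[valid]) <= 0) {
    v <- polarization_vector(NA, 0, "edu_centroid")
    attr(v, "undefined") <- TRUE
    return(v)
  }
  wc <- weighted_centroid_um(as_plain(nrm), valid, pixel_size)
  d <- wc - geo
  len <- sqrt(sum(d^2))
  if (len == 0) {
    v <- polarization_vector(NA, 0, "edu_centroid")
    attr(v, "undefined") <- TRUE
    return(v)
  }
  angle <- norm_angle(unname(atan2(d[2], d[1])) * 180 / pi)
  feret <- feret_extent(mask, angle, pixel_size)
  polarization_vector(angle, len / feret, "edu_centroid")
}

#' Positivity call for a colonoid and marker channel
#'
#' A colonoid is positive for a marker when at least `area_fraction` of its
#' in-mask pixels exceed `pixel_intensity_threshold` (ties count as
#' positive). The channel should be top-hat filtered beforehand; thresholds
#' are calibration inputs, see [calibrate_positivity_threshold()]. Default
#' area fractions in the pipeline: Sox9EGFP 0.25, Muc-2 0.10, EdU 0.25.
#'
#' @param channel_img filtered marker intensity matrix.
#' @param mask logical object mask.
#' @param pixel_intensity_threshold per-pixel positivity threshold.
#' @param area_fraction minimum positive-pixel fraction.
#' @return logical.
#' @export
positivity <- function(channel_img, mask, pixel_intensity_threshold,
                       area_fraction) {
  stopifnot(any(mask), area_fraction >= 0, area_fraction <= 1)
  mean(channel_img[mask] > pixel_intensity_threshold) >= area_fraction
}

#' Calibrate a per-pixel positivity threshold from a negative control
#'
#' Returns a high quantile of the (top-hat filtered) intensities of
#' negative-control pixels -- either a control image or the out-of-object
#' pixels of the analysis image.
#'
#' @param img filtered intensity matrix.
#' @param mask optional logical matrix of object pixels to exclude.
#' @param prob quantile used as threshold.
#' @return numeric threshold.
#' @export
calibrate_positivity_threshold <- function(img, mask = NULL, prob = 0.995) {
  v <- if (is.null(mask)) as.vector(img) else img[!mask]
  quantile(v, prob, names = FALSE)
}

#' Measurement configuration
#'
#' @param slice_width_um Sox9 slice width, um.
#' @param min_area_um2 minimum area for the rotation-slope metric, um^2.
#' @param tophat_radius_um top-hat radius for positivity filtering, um.
#' @param positivity_fractions named fractions for `sox9`, `muc2`, `edu`.
#' @param positivity_thresholds optional named per-pixel thresholds; missing
#'   entries are calibrated from out-of-object pixels.
#' @param ratio_floor_frac denominator floor for ratio images.
#' @param subtract_background estimate (out-of-object median) and subtract a
#'   flat background from each fluorescence channel before ratios?
#' @return a named list.
#' @export
measure_config <- function(slice_width_um = 20, min_area_um2 = 1000,
                           tophat_radius_um = 150,
                           positivity_fractions = c(sox9 = 0.25, muc2 = 0.10,
                                                    edu = 0.25),
                           positivity_thresholds = NULL,
                           ratio_floor_frac = 0.01,
                           subtract_background = TRUE) {
  list(slice_width_um = slice_width_um, min_area_um2 = min_area_um2,
       tophat_radius_um = tophat_radius_um,
       positivity_fractions = positivity_fractions,
       positivity_thresholds = positivity_thresholds,
       ratio_floor_frac = ratio_floor_frac,
       subtract_background = subtract_background)
}

#' Measure every labeled colonoid in a scene
#'
#' One record per label: area (the cell-number proxy), centroid position (um
#' from the sink interface at the left image edge), integrated intensity per
#' available channel, positivity flags (Sox9EGFP on the EGFP channel, Muc-2,
#' EdU; top-hat filtered, thresholds calibrated from out-of-object pixels
#' unless supplied), the rotation-slope Sox9EGFP vector (EGFP/DsRed) and the
#' centroid-offset EdU vector (EdU/Hoechst). Fields whose channels are
#' missing are NA and reported via a message.
#'
#' @param channels named list of co-registered intensity matrices; recognized
#'   names: `dsred`, `egfp`, `hoechst`, `edu`, `muc2`.
#' @param labels integer label matrix from [segment_colonoids()].
#' @param config a [measure_config()].
#' @param pixel_size um/px.
#' @return data.frame with one row per label.
#' @export
measure_colonoids <- function(channels, labels, config = measure_config(),
                              pixel_size = px_size(labels)) {
  lab <- as_plain(labels)
  n <- max(lab)
  chan_names <- c("dsred", "egfp", "hoechst", "edu", "muc2")
  have <- intersect(chan_names, names(channels))
  missing_ch <- setdiff(chan_names, have)
  if (length(missing_ch))
    message("missing channel(s): ", paste(missing_ch, collapse = ", "),
            "; dependent fields will be NA")
  empty <- data.frame(label = integer(), area_um2 = double(),
                      centroid_x_um = double(), centroid_y_um = double())
  if (n == 0) return(empty)
  any_mask <- lab > 0
  bg <- sapply(have, function(ch) median(channels[[ch]][!any_mask]))
  sub_bg <- function(ch) {
    img <- as_plain(channels[[ch]])
    if (config$subtract_background) pmax(img - bg[[ch]], 0) else img
  }
  # top-hat filtered marker channels + thresholds for positivity
  filt <- list(); thr <- list()
  for (mk in c("sox9", "muc2", "edu")) {
    ch <- c(sox9 = "egfp", muc2 = "muc2", edu = "edu")[[mk]]
    if (!ch %in% have) next
    filt[[mk]] <- tophat_filter(channels[[ch]], config$tophat_radius_um,
                                pixel_size)
    thr[[mk]] <- config$positivity_thresholds[[mk]] %||%
      calibrate_positivity_threshold(filt[[mk]], any_mask)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- lab == i
    cen <- mask_centroid_um(m, pixel_size)
    rec <- list(label = i, area_um2 = sum(m) * pixel_size^2,
                centroid_x_um = cen[["x"]], centroid_y_um = cen[["y"]])
    for (ch in chan_names)
      rec[[paste0("int_", ch)]] <-
        if (ch %in% have) sum(channels[[ch]][m]) else NA_real_
    for (mk in c("sox9", "muc2", "edu"))
      rec[[paste0("pos_", mk)]] <- if (!is.null(filt[[mk]]))
        positivity(filt[[mk]], m, thr[[mk]],
                   config$positivity_fractions[[mk]]) else NA
    rec$sox9_angle_deg <- rec$sox9_magnitude <- NA_real_
    rec$edu_angle_deg <- rec$edu_magnitude <- NA_real_
    if (all(c("egfp", "dsred") %in% have) &&
        rec$area_um2 >= config$min_area_um2) {
      ratio <- suppressMessages(
        ratio_image(sub_bg("egfp"), sub_bg("dsred"), m,
                    config$ratio_floor_frac))
      v <- sox9_polarization(ratio, m, pixel_size, config$slice_width_um,
                             config$min_area_um2)
      rec$sox9_angle_deg <- v$angle_deg; rec$sox9_magnitude <- v$magnitude
    }
    if (all(c("edu", "hoechst") %in% have)) {
      v <- suppressMessages(
        edu_polarization(sub_bg("edu"), sub_bg("hoechst"), m, pixel_size,
                         config$ratio_floor_frac))
      rec$edu_angle_deg <- v$angle_deg; rec$edu_magnitude <- v$magnitude
    }
    rows[[i]] <- as.data.frame(rec)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
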