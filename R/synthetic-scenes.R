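#' Specify one synthetic colonoid body
#'
#' Describes an elliptical colonoid with known ground-truth polarization: a
#' uniform DsRed level over the body, an EGFP/DsRed ratio with a linear
#' gradient of `egfp_slope` (ratio units per um) along `egfp_angle`, punctate
#' EdU whose intensity-weighted centroid is offset from the geometric centroid
#' by `edu_centroid_offset_frac` of the body length along `edu_angle`, and an
#' optional Muc-2 cap covering `muc2_fraction` of the body pixels.
#'
#' @param center `c(row, col)` body centre, px.
#' @param semi_axes `c(a, b)` ellipse semi-axes, px; `a` lies along
#'   `orientation`.
#' @param orientation ellipse orientation, degrees CCW from +x.
#' @param dsred_level DsRed intensity inside the body.
#' @param egfp_base,egfp_slope,egfp_angle EGFP/DsRed ratio at the body centre,
#'   its gradient (ratio units per um) and gradient direction (deg).
#' @param n_edu_puncta number of Gaussian EdU puncta (sigma = 2 px).
#' @param edu_centroid_offset_frac true EdU centroid offset as a fraction of
#'   body length along `edu_angle`; must lie in `[0, 0.5)`.
#' @param edu_angle direction of the EdU offset, deg.
#' @param muc2_fraction fraction of body pixels carrying Muc-2 signal.
#' @return a `colonoid_spec` list.
#' @export
colonoid_spec <- function(center, semi_axes, orientation = 0,
                          dsred_level = 200,
                          egfp_base = 0.5, egfp_slope = 0, egfp_angle = 0,
                          n_edu_puncta = 30, edu_centroid_offset_frac = 0,
                          edu_angle = 0, muc2_fraction = 0) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes > 0),
            dsred_level > 0, egfp_base >= 0,
            edu_centroid_offset_frac >= 0, edu_centroid_offset_frac < 0.5,
            muc2_fraction >= 0, muc2_fraction <= 1, n_edu_puncta >= 0)
  structure(list(center = center, semi_axes = semi_axes,
                 orientation = orientation, dsred_level = dsred_level,
                 egfp_base = egfp_base, egfp_slope = egfp_slope,
                 egfp_angle = norm_angle(egfp_angle),
                 n_edu_puncta = as.integer(n_edu_puncta),
                 edu_centroid_offset_frac = edu_centroid_offset_frac,
                 edu_angle = norm_angle(edu_angle),
                 muc2_fraction = muc2_fraction),
            class = "colonoid_spec")
}

#' Specify a synthetic multi-channel scene
#'
#' @param image_shape `c(rows, cols)` in px.
#' @param pixel_size um/px.
#' @param colonoids list of [colonoid_spec()] objects.
#' @param background_level additive background intensity common to all
#'   fluorescence channels.
#' @param illumination_gradient uneven-illumination slope, intensity per px
#'   along `illumination_angle`.
#' @param illumination_angle direction of the illumination ramp, deg.
#' @param noise list with `poisson_scale` (counts per intensity unit; 0
#'   disables shot noise) and `gaussian_sd` (additive read noise sd).
#' @param n_debris number of non-cellular debris objects: dark blobs in
#'   brightfield carrying only faint DsRed over a footprint well below the
#'   brightfield footprint.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   scenes.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(256, 256), pixel_size = 1,
                       colonoids = list(), background_level = 20,
                       illumination_gradient = 0, illumination_angle = 0,
                       noise = list(poisson_scale = 1, gaussian_sd = 2),
                       n_debris = 0, rng_seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape > 0), pixel_size > 0,
            background_level >= 0, noise$poisson_scale >= 0,
            noise$gaussian_sd >= 0, n_debris >= 0)
  if (length(colonoids) && !all(vapply(colonoids, inherits, TRUE, "colonoid_spec")))
    stop("colonoids must be a list of colonoid_spec objects")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, colonoids = colonoids,
                 background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 illumination_angle = norm_angle(illumination_angle),
                 noise = noise, n_debris = as.integer(n_debris),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# filled ellipse mask in the y-up pixel coordinate frame
ellipse_mask <- function(shape, center, semi_axes, orientation_deg = 0) {
  nr <- shape[1]; nc <- shape[2]
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  dx <- cc - center[2]
  dy <- -(rr - center[1])
  th <- orientation_deg * pi / 180
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

# render Gaussian puncta (positions in px rows/cols, amplitudes) onto a canvas
render_puncta <- function(shape, pos, amp, sigma = 2) {
  img <- matrix(0, shape[1], shape[2])
  w <- ceiling(4 * sigma)
  for (i in seq_len(nrow(pos))) {
    r0 <- pos[i, 1]; c0 <- pos[i, 2]
    rs <- max(1, floor(r0 - w)):min(shape[1], ceiling(r0 + w))
    cs <- max(1, floor(c0 - w)):min(shape[2], ceiling(c0 + w))
    g <- outer(exp(-(rs - r0)^2 / (2 * sigma^2)),
               exp(-(cs - c0)^2 / (2 * sigma^2)))
    img[rs, cs] <- img[rs, cs] + amp[i] * g
  }
  img
}

# place EdU puncta so the in-mask intensity-weighted centroid of the rendered,
# mask-truncated channel sits at the requested offset from the mask centroid
place_edu <- function(mask, n, offset_frac, angle_deg, pixel_size,
                      level = 200, sigma = 2) {
  shape <- dim(mask)
  if (n == 0) return(matrix(0, shape[1], shape[2]))
  cen <- mask_centroid_um(mask, pixel_size)
  len <- feret_extent(mask, angle_deg, pixel_size)
  a <- angle_deg * pi / 180
  target <- cen + offset_frac * len * c(cos(a), sin(a))       # um, y up
  xy <- mask_coords_um(mask, pixel_size)
  d2 <- (xy[, 1] - target[1])^2 + (xy[, 2] - target[2])^2
  keep <- order(d2)[seq_len(min(length(d2), max(5L * n, 40L)))]
  pick <- keep[sample.int(length(keep), n, replace = n > length(keep))]
  # px positions (row, col) from um coords
  pos <- cbind(nrow(mask) - (xy[pick, 2] / pixel_size - 0.5),
               xy[pick, 1] / pixel_size + 0.5)
  amp <- level * runif(n, 0.5, 1)
  img <- NULL
  for (iter in 1:25) {
    img <- render_puncta(shape, pos, amp, sigma)
    img[!mask] <- 0
    got <- weighted_centroid_um(img, mask, pixel_size)
    err <- target - got
    if (sqrt(sum(err^2)) < 0.05 * pixel_size) break
    pos[, 1] <- pos[, 1] - err[2] / pixel_size   # row shift: y error, sign flip
    pos[, 2] <- pos[, 2] + err[1] / pixel_size
    # clamp each punctum to the nearest in-mask pixel
    idx <- which(mask, arr.ind = TRUE)
    for (i in seq_len(nrow(pos))) {
      rr <- round(pos[i, 1]); cc <- round(pos[i, 2])
      rr <- min(max(rr, 1), shape[1]); cc <- min(max(cc, 1), shape[2])
      if (!mask[rr, cc]) {
        j <- which.min((idx[, 1] - pos[i, 1])^2 + (idx[, 2] - pos[i, 2])^2)
        pos[i, ] <- idx[j, ]
      }
    }
  }
  img
}

#' Render a synthetic multi-channel microscopy scene with ground truth
#'
#' Produces six co-registered channels (`dsred`, `egfp`, `hoechst`, `edu`,
#' `muc2`, `brightfield`) both noise-free (`clean`, pure signal: no background,
#' illumination or noise) and degraded (`channels`: signal + background +
#' illumination ramp + Poisson shot noise + Gaussian read noise), together
#' with the ground-truth label map and per-colonoid parameter table. Inside
#' each body the clean EGFP channel equals
#' `dsred_level * max(egfp_base + egfp_slope * d, 0)` with `d` the signed um
#' distance from the body centroid along `egfp_angle`. Debris appears dark in
#' brightfield with a faint-DsRed footprint at most ~36% of its brightfield
#' footprint area, so the 20%-larger brightfield rule removes it.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `channels`, `clean` (named lists of
#'   [pixel_grid()]s), and `truth` (list: `label_map`, `debris_bf`,
#'   `debris_fluor` label matrices and a `table` data.frame with columns
#'   `label, true_angle_deg, true_slope, true_edu_offset, true_edu_angle,
#'   area_um2`).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$rng_seed, make_scene_impl(spec))
}

make_scene_impl <- function(spec) {
  shape <- spec$image_shape
  ps <- spec$pixel_size
  nr <- shape[1]; nc <- shape[2]
  zero <- function() matrix(0, nr, nc)
  clean <- list(dsred = zero(), egfp = zero(), hoechst = zero(),
                edu = zero(), muc2 = zero(), brightfield = zero())
  label_map <- matrix(0L, nr, nc)
  hoechst_level <- 150
  bf_bg <- 230

  body <- matrix(FALSE, nr, nc)
  tab <- data.frame(label = integer(), true_angle_deg = double(),
                    true_slope = double(), true_edu_offset = double(),
                    true_edu_angle = double(), area_um2 = double())
  for (i in seq_along(spec$colonoids)) {
    cs <- spec$colonoids[[i]]
    m <- ellipse_mask(shape, cs$center, cs$semi_axes, cs$orientation)
    if (!any(m)) stop("colonoid ", i, " renders no pixels")
    if (any(m & body)) stop("colonoid bodies overlap; ground truth would be ambiguous")
    body <- body | m
    label_map[m] <- i
    clean$dsred[m] <- cs$dsred_level
    cen <- mask_centroid_um(m, ps)
    xy <- mask_coords_um(m, ps)
    a <- cs$egfp_angle * pi / 180
    d <- (xy[, 1] - cen[1]) * cos(a) + (xy[, 2] - cen[2]) * sin(a)
    clean$egfp[m] <- cs$dsred_level * pmax(cs$egfp_base + cs$egfp_slope * d, 0)
    clean$hoechst[m] <- hoechst_level
    clean$edu <- clean$edu +
      place_edu(m, cs$n_edu_puncta, cs$edu_centroid_offset_frac,
                cs$edu_angle, ps)
    if (cs$muc2_fraction > 0) {
      th <- cs$orientation * pi / 180
      proj <- xy[, 1] * cos(th) + xy[, 2] * sin(th)
      cut <- quantile(proj, 1 - cs$muc2_fraction, names = FALSE)
      sel <- which(m)[proj >= cut]
      clean$muc2[sel] <- 120
    }
    tab <- rbind(tab, data.frame(
      label = i, true_angle_deg = cs$egfp_angle, true_slope = cs$egfp_slope,
      true_edu_offset = cs$edu_centroid_offset_frac,
      true_edu_angle = cs$edu_angle, area_um2 = sum(m) * ps^2))
  }

  # brightfield: bright background, bodies slightly dark
  clean$brightfield[] <- bf_bg
  clean$brightfield[body] <- bf_bg * 0.72

  # debris: dark brightfield blobs carrying faint DsRed over a shrunken footprint
  debris_bf <- matrix(0L, nr, nc)
  debris_fl <- matrix(0L, nr, nc)
  placed <- 0L; tries <- 0L
  while (placed < spec$n_debris && tries < 200L) {
    tries <- tries + 1L
    ax <- runif(2, 30, 45) / ps                       # semi-axes in px
    ctr <- c(runif(1, max(ax) + 2, nr - max(ax) - 2),
             runif(1, max(ax) + 2, nc - max(ax) - 2))
    ori <- runif(1, 0, 180)
    bf_m <- ellipse_mask(shape, ctr, ax, ori)
    # clearance keeps debris from abutting a body: touching footprints merge
    # in brightfield and make the ground truth for the 20% rule ambiguous
    guard <- ellipse_mask(shape, ctr, ax + 8 / ps, ori)
    if (any(guard & (body | debris_bf > 0))) next
    placed <- placed + 1L
    fl_m <- ellipse_mask(shape, ctr, 0.6 * ax, 0)
    debris_bf[bf_m] <- placed
    debris_fl[fl_m] <- placed
    clean$brightfield[bf_m] <- bf_bg * 0.55
    lev <- if (length(spec$colonoids))
      0.6 * mean(vapply(spec$colonoids, `[[`, 0, "dsred_level")) else 100
    clean$dsred[fl_m] <- pmax(clean$dsred[fl_m], lev)
  }
  if (placed < spec$n_debris)
    warning("placed only ", placed, " of ", spec$n_debris, " debris objects")

  # degrade: background + illumination ramp on fluorescence channels, then noise
  ia <- spec$illumination_angle * pi / 180
  ccm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rrm <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  ramp <- spec$illumination_gradient *
    ((ccm - (nc + 1) / 2) * cos(ia) - (rrm - (nr + 1) / 2) * sin(ia))
  degrade <- function(img, fluor = TRUE) {
    out <- img
    if (fluor) out <- out + spec$background_level + ramp
    out <- pmax(out, 0)
    if (spec$noise$poisson_scale > 0)
      out <- matrix(rpois(length(out), out * spec$noise$poisson_scale) /
                      spec$noise$poisson_scale, nr, nc)
    if (spec$noise$gaussian_sd > 0)
      out <- out + rnorm(length(out), 0, spec$noise$gaussian_sd)
    pmax(out, 0)
  }
  channels <- list(dsred = degrade(clean$dsred),
                   egfp = degrade(clean$egfp),
                   hoechst = degrade(clean$hoechst),
                   edu = degrade(clean$edu),
                   muc2 = degrade(clean$muc2),
                   brightfield = degrade(clean$brightfield, fluor = FALSE))
  channels <- lapply(channels, pixel_grid, pixel_size = ps)
  clean <- lapply(clean, pixel_grid, pixel_size = ps)
  list(channels = channels, clean = clean,
       truth = list(label_map = pixel_grid(label_map, ps),
                    debris_bf = debris_bf, debris_fluor = debris_fl,
                    table = tab))
}

#' Random multi-colonoid scene specification
#'
#' Convenience builder for property tests and benchmarks: places `n_colonoids`
#' non-overlapping elliptical bodies on a jittered grid, each with the stated
#' true EGFP gradient and EdU offset drawn uniformly (angles from 0-360 deg),
#' plus `n_debris` debris objects.
#'
#' @param seed integer RNG seed (also stored as the scene's `rng_seed`).
#' @param n_colonoids,n_debris object counts.
#' @param image_shape,pixel_size scene geometry.
#' @param egfp_slope,edu_offset true polarization magnitudes given to every
#'   colonoid (angles are randomized per colonoid).
#' @param noise noise list as in [scene_spec()].
#' @return a [scene_spec()].
#' @export
random_scene_spec <- function(seed, n_colonoids = 3, n_debris = 0,
                              image_shape = c(360, 360), pixel_size = 1,
                              egfp_slope = 0.01, edu_offset = 0.25,
                              noise = list(poisson_scale = 1, gaussian_sd = 2)) {
  withr::with_seed(seed, {
    ngrid <- ceiling(sqrt(n_colonoids))
    cells <- expand.grid(gr = seq_len(ngrid), gc = seq_len(ngrid))
    cells <- cells[sample.int(nrow(cells), n_colonoids), , drop = FALSE]
    step <- image_shape / (ngrid + 0.15)
    cols <- vector("list", n_colonoids)
    for (i in seq_len(n_colonoids)) {
      ctr <- c((cells$gr[i] - 0.5) * step[1] + runif(1, -4, 4) + 4,
               (cells$gc[i] - 0.5) * step[2] + runif(1, -4, 4) + 4)
      # body scale matches the reported median colonoid area (~13,000 um^2
      # at 1 um/px for a full-size scene) while keeping bodies separated
      ax <- sort(runif(2, 0.30, 0.42) * min(step))
      cols[[i]] <- colonoid_spec(
        center = ctr, semi_axes = c(ax[2], ax[1]),
        orientation = runif(1, 0, 180),
        egfp_base = 0.6, egfp_slope = egfp_slope,
        egfp_angle = runif(1, 0, 360),
        n_edu_puncta = 35, edu_centroid_offset_frac = edu_offset,
        edu_angle = runif(1, 0, 360), muc2_fraction = 0.15)
    }
    scene_spec(image_shape = image_shape, pixel_size = pixel_size,
               colonoids = cols, n_debris = n_debris, noise = noise,
               rng_seed = seed)
  })
}
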