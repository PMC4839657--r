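#' White top-hat background removal
#'
#' Image minus its morphological opening with a disk structuring element of
#' physical radius `radius_um`, removing background fluorescence and slowly
#' varying uneven illumination while preserving objects smaller than the
#' element.
#'
#' @param img intensity matrix (um/px taken from its `pixel_size` attribute
#'   unless given).
#' @param radius_um disk radius, um; must convert to at least 1 px.
#' @param pixel_size um/px.
#' @return filtered [pixel_grid()].
#' @export
tophat_filter <- function(img, radius_um = 150, pixel_size = px_size(img)) {
  stopifnot(radius_um > 0)
  r_px <- radius_um / pixel_size
  if (r_px < 1) stop("top-hat radius below 1 px at this pixel size")
  brush <- EBImage::makeBrush(2L * floor(r_px) + 1L, shape = "disc")
  # EBImage grayscale morphology assumes intensities in [0, 1]
  scale <- max(as_plain(img), 1e-12)
  out <- EBImage::whiteTopHat(as_plain(img) / scale, brush) * scale
  pixel_grid(matrix(EBImage::imageData(out), nrow(img), ncol(img)), pixel_size)
}

#' Minimum cross-entropy (Li) threshold
#'
#' Selects the threshold minimizing the cross entropy between the image and
#' its two-class approximation by the class means (Li's criterion), searched
#' exhaustively over a histogram of `n_bins` levels. Pixels strictly above
#' the threshold are foreground.
#'
#' @param img intensity matrix with at least two distinct values.
#' @param n_bins histogram resolution of the threshold search.
#' @return logical foreground mask; the threshold is attached as attribute
#'   `"threshold"`.
#' @export
threshold_min_cross_entropy <- function(img, n_bins = 256) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) stop("no threshold exists: image is constant")
  # histogram over n_bins levels; candidate thresholds between bins
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  g <- (br[-1] + br[-(n_bins + 1L)]) / 2
  cn <- cumsum(h); cm <- cumsum(h * g)
  n_tot <- cn[n_bins]; m_tot <- cm[n_bins]
  k <- seq_len(n_bins - 1L)                       # split after bin k
  mu1 <- cm[k] / pmax(cn[k], 1)
  mu2 <- (m_tot - cm[k]) / pmax(n_tot - cn[k], 1)
  term <- function(m, mu) ifelse(m > 0 & mu > 0, m * log(mu), 0)
  eta <- -(term(cm[k], mu1) + term(m_tot - cm[k], mu2))
  valid <- cn[k] > 0 & cn[k] < n_tot
  if (!any(valid)) stop("no threshold exists: degenerate histogram")
  eta[!valid] <- Inf
  thr <- br[which.min(eta) + 1L]
  structure(matrix(v > thr, nrow(img), ncol(img)), threshold = thr,
            pixel_size = px_size(img))
}

#' Fill holes and remove small objects from a binary mask
#'
#' Interior holes are filled; connected components with area strictly below
#' `min_area_um2` are removed (an object of exactly the minimum area is
#' kept).
#'
#' @param mask logical matrix.
#' @param min_area_um2 minimum retained object area, um^2.
#' @param pixel_size um/px.
#' @return cleaned logical mask.
#' @export
clean_mask <- function(mask, min_area_um2 = 1000, pixel_size = px_size(mask)) {
  stopifnot(is.logical(c(mask)))
  filled <- EBImage::imageData(EBImage::fillHull(as_plain(mask) * 1L))
  lab <- EBImage::imageData(EBImage::bwlabel(filled))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0]) * pixel_size^2
    drop <- which(areas < min_area_um2)
    filled[lab %in% drop] <- 0L
  }
  structure(matrix(filled > 0, nrow(mask), ncol(mask)),
            pixel_size = pixel_size)
}

#' Chan-Vese two-phase active-contour refinement
#'
#' Minimizes the two-phase piecewise-constant Chan-Vese energy on the
#' brightfield image starting from an initial mask: each sweep reassigns
#' pixels to the phase whose current mean intensity is closer (the lambda1 =
#' lambda2 = 1 data term) and then applies `smooth_passes` majority-filter
#' passes, a morphological surrogate for the curvature penalty. Iteration
#' stops when the region changes by less than `tol` of its size, or at
#' `max_iter` with a warning flag (attribute `"converged"`). A brightfield
#' image whose two phases have indistinguishable means is degenerate: the
#' initial mask is returned with a warning.
#'
#' @param brightfield intensity matrix.
#' @param init_mask non-empty logical initialization.
#' @param smooth_passes majority-filter passes per sweep (curvature weight).
#' @param max_iter maximum sweeps.
#' @param tol relative region change declaring convergence.
#' @return logical mask with attribute `"converged"`.
#' @export
chan_vese_refine <- function(brightfield, init_mask, smooth_passes = 1,
                             max_iter = 200, tol = 0.001) {
  stopifnot(any(init_mask))
  img <- as_plain(brightfield)
  u <- as_plain(init_mask) > 0
  scale <- diff(range(img))
  kern <- matrix(1 / 9, 3, 3)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    c1 <- mean(img[u]); c2 <- if (all(u)) c1 else mean(img[!u])
    if (!is.finite(c1) || !is.finite(c2) || abs(c1 - c2) <= 1e-8 * max(scale, 1)) {
      warning("degenerate Chan-Vese energy: phases indistinguishable; returning initialization")
      return(structure(as_plain(init_mask) > 0, converged = FALSE,
                       pixel_size = px_size(brightfield)))
    }
    u_new <- (img - c1)^2 < (img - c2)^2
    for (s in seq_len(smooth_passes)) {
      sm <- EBImage::imageData(EBImage::filter2(u_new * 1, kern,
                                                boundary = "replicate"))
      u_new <- sm > 0.5
    }
    changed <- sum(u_new != u)
    denom <- max(sum(u), 1)
    u <- u_new
    if (changed / denom < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Chan-Vese did not converge within ", max_iter, " iterations")
  structure(u, converged = converged, pixel_size = px_size(brightfield))
}

# boundary pixel count (4-connectivity) of each label
label_perimeters <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  edge <- (pad[1:nr, 2:(nc + 1)] != core) | (pad[3:(nr + 2), 2:(nc + 1)] != core) |
    (pad[2:(nr + 1), 1:nc] != core) | (pad[2:(nr + 1), 3:(nc + 2)] != core)
  tab <- tabulate(core[edge & core > 0], nbins = max(labels, 1))
  tab
}

#' Remove non-cellular debris and border objects from a segmentation
#'
#' A fluorescence-segmented object is classified as debris and removed when
#' its matched brightfield object (maximal pixel overlap) has a region
#' measure more than `threshold` larger than the fluorescence measure --
#' degrading or non-cellular material scatters light over a footprint well
#' beyond its residual fluorescence. Objects touching the image border are
#' also removed. Fluorescence objects with no overlapping brightfield object
#' are kept and reported.
#'
#' @param fluor_labels integer label matrix from fluorescence segmentation.
#' @param bf_labels integer label matrix from brightfield segmentation.
#' @param threshold excess fraction above which an object is debris.
#' @param compare `"area"` (enclosed region area, default; robust to contour
#'   roughness) or `"perimeter"` (boundary length).
#' @param drop_border remove objects touching the image border?
#' @return relabeled integer matrix; attributes `"removed_debris"`,
#'   `"removed_border"`, `"unmatched"` give the original labels affected.
#' @export
remove_debris <- function(fluor_labels, bf_labels, threshold = 0.20,
                          compare = c("area", "perimeter"),
                          drop_border = TRUE) {
  stopifnot(all(dim(fluor_labels) == dim(bf_labels)))
  compare <- match.arg(compare)
  fl <- as_plain(fluor_labels); bf <- as_plain(bf_labels)
  n <- max(fl)
  keep <- rep(TRUE, n)
  unmatched <- integer(); debris <- integer(); border <- integer()
  if (n > 0) {
    f_meas <- if (compare == "area") tabulate(fl[fl > 0], nbins = n)
              else label_perimeters(fl)
    b_meas <- if (compare == "area") tabulate(bf[bf > 0], nbins = max(bf, 1))
              else label_perimeters(bf)
    for (i in seq_len(n)) {
      in_i <- fl == i
      ov <- bf[in_i]
      ov <- ov[ov > 0]
      if (!length(ov)) { unmatched <- c(unmatched, i); next }
      j <- as.integer(names(which.max(table(ov))))
      if (b_meas[j] > (1 + threshold) * f_meas[i]) {
        keep[i] <- FALSE; debris <- c(debris, i)
      }
    }
    if (drop_border) {
      nr <- nrow(fl); nc <- ncol(fl)
      edge_labels <- unique(c(fl[1, ], fl[nr, ], fl[, 1], fl[, nc]))
      edge_labels <- setdiff(edge_labels, 0L)
      border <- intersect(which(keep), edge_labels)
      keep[edge_labels] <- FALSE
    }
  }
  out <- matrix(0L, nrow(fl), ncol(fl))
  new_id <- cumsum(keep) * keep
  pos <- fl > 0
  out[pos] <- new_id[fl[pos]]
  structure(out, removed_debris = debris, removed_border = border,
            unmatched = unmatched, pixel_size = px_size(fluor_labels))
}

#' Segmentation configuration
#'
#' @param tophat_radius_um top-hat structuring-element radius, um.
#' @param min_area_um2 minimum colonoid area, um^2.
#' @param debris_threshold brightfield-excess fraction defining debris.
#' @param debris_compare `"area"` or `"perimeter"`.
#' @param cv_smooth_passes,cv_max_iter,cv_tol Chan-Vese controls.
#' @return a named list.
#' @export
segment_config <- function(tophat_radius_um = 150, min_area_um2 = 1000,
                           debris_threshold = 0.20,
                           debris_compare = "area",
                           cv_smooth_passes = 1, cv_max_iter = 200,
                           cv_tol = 0.001) {
  list(tophat_radius_um = tophat_radius_um, min_area_um2 = min_area_um2,
       debris_threshold = debris_threshold, debris_compare = debris_compare,
       cv_smooth_passes = cv_smooth_passes, cv_max_iter = cv_max_iter,
       cv_tol = cv_tol)
}

#' Segment colonoids from fluorescence with brightfield debris removal
#'
#' Full segmentation pipeline: top-hat background removal, minimum
#' cross-entropy thresholding, hole filling and small-object removal on the
#' fluorescence channel (DsRed or Hoechst); Chan-Vese refinement on the
#' brightfield image initialized from the fluorescence mask; removal of
#' debris (brightfield footprint > 20% larger than fluorescence) and
#' border-touching objects; sequential labeling.
#'
#' @param fluor DsRed or Hoechst intensity matrix.
#' @param brightfield co-registered brightfield matrix (NULL skips the debris
#'   step).
#' @param config a [segment_config()].
#' @param pixel_size um/px.
#' @return integer label matrix (0 = background) with `pixel_size` attribute;
#'   an empty segmentation is a valid all-zero map.
#' @export
segment_colonoids <- function(fluor, brightfield = NULL,
                              config = segment_config(),
                              pixel_size = px_size(fluor)) {
  th <- tophat_filter(fluor, config$tophat_radius_um, pixel_size)
  mask <- threshold_min_cross_entropy(th)
  mask <- clean_mask(mask, config$min_area_um2, pixel_size)
  fl_lab <- EBImage::imageData(EBImage::bwlabel(mask * 1L))
  fl_lab <- matrix(as.integer(fl_lab), nrow(mask), ncol(mask))
  attr(fl_lab, "pixel_size") <- pixel_size
  if (max(fl_lab) == 0) {
    message("segmentation empty: no objects above ", config$min_area_um2, " um^2")
    return(structure(fl_lab, pixel_size = pixel_size))
  }
  out <- if (is.null(brightfield)) {
    # border rule still applies without a brightfield channel
    remove_debris(fl_lab, fl_lab, threshold = Inf,
                  compare = config$debris_compare)
  } else {
    cv <- chan_vese_refine(brightfield, mask,
                           smooth_passes = config$cv_smooth_passes,
                           max_iter = config$cv_max_iter, tol = config$cv_tol)
    bf_lab <- EBImage::imageData(EBImage::bwlabel(cv * 1L))
    bf_lab <- matrix(as.integer(bf_lab), nrow(mask), ncol(mask))
    remove_debris(fl_lab, bf_lab, threshold = config$debris_threshold,
                  compare = config$debris_compare)
  }
  if (max(out) == 0)
    message("segmentation empty after debris/border removal")
  out
}
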