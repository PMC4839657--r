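#' Log transform with Q-Q normality adequacy check
#'
#' Natural-log transforms positive values and reports the adjusted R-squared
#' of the ordered transformed values regressed on standard normal quantiles
#' (the Q-Q line fit). An adjusted R-squared of at least 0.91 is taken as
#' adequate log-normality for downstream t-tests.
#'
#' @param values positive numeric vector (length >= 3).
#' @param r2_min adequacy cutoff.
#' @return list with `transformed` (log values, original order),
#'   `r_squared_adj`, and `adequate`.
#' @export
log_qq_check <- function(values, r2_min = 0.91) {
  bad <- sum(!is.finite(values) | values <= 0)
  if (bad > 0)
    stop(bad, " non-positive or non-finite value(s); log transform undefined")
  if (length(values) < 3) stop("need at least 3 values")
  y <- log(values)
  n <- length(y)
  r2 <- cor(sort(y), qnorm(ppoints(n)))^2
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(transformed = y, r_squared_adj = r2_adj, adequate = r2_adj >= r2_min)
}

#' Holm-Sidak step-down multiple-comparison decisions
#'
#' Sorts p-values ascending and rejects the i-th smallest while
#' `p_(i) <= 1 - (1 - alpha)^(1/(m - i + 1))`; the first failure retains all
#' remaining hypotheses (monotone decisions).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return data.frame in the input order with columns `p`, `critical`
#'   (the Sidak step-down bound applied to each), `reject`.
#' @export
holm_sidak <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues))
    return(data.frame(p = double(), critical = double(), reject = logical()))
  stopifnot(all(pvalues >= 0 & pvalues <= 1), alpha > 0, alpha < 1)
  m <- length(pvalues)
  ord <- order(pvalues)
  crit <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  rej_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (pvalues[ord[i]] <= crit[i]) rej_sorted[i] <- TRUE else break
  }
  out <- data.frame(p = pvalues, critical = NA_real_, reject = NA)
  out$critical[ord] <- crit
  out$reject[ord] <- rej_sorted
  out
}

#' Pairwise Welch t-tests on log-transformed values with Holm-Sidak control
#'
#' The full comparison workflow: values are log-transformed
#' (adequacy reported per group), all pairwise two-sided Welch t-tests are
#' computed, and Holm-Sidak step-down decisions applied.
#'
#' @param values positive numeric vector.
#' @param groups factor/character of the same length.
#' @param alpha family-wise error rate.
#' @return data.frame with one row per pair: `group1`, `group2`, `p`,
#'   `critical`, `reject`.
#' @export
compare_conditions <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2) stop("need at least two groups")
  logv <- log_qq_check(values)$transformed
  pairs <- utils::combn(lv, 2)
  p <- apply(pairs, 2, function(g)
    t.test(logv[groups == g[1]], logv[groups == g[2]])$p.value)
  dec <- holm_sidak(p, alpha)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = p,
             critical = dec$critical, reject = dec$reject)
}

#' Average polarization vectors with uncertainty propagation
#'
#' Vectors are averaged through their Cartesian components (so dispersed
#' angles cancel, as in the compass-plot mean arrows); the mean angle and
#' resultant magnitude are reported with standard deviations propagated to
#' first order from the component standard deviations. The arithmetic mean
#' and SD of the magnitudes and the circular mean of the angles are also
#' returned -- these are the printed per-condition "magnitude +/- sd" and
#' "angle +/- sd" summaries and feed condition fold-ratios.
#'
#' @param angles_deg vector of angles, deg; NA angles (undefined vectors) are
#'   excluded and counted.
#' @param magnitudes vector of non-negative magnitudes.
#' @param metric metric kind carried through to the output.
#' @return list: `angle_deg`, `magnitude` (resultant), `sd_angle_deg`,
#'   `sd_magnitude` (propagated), `mag_mean`, `mag_sd`, `angle_mean_deg`
#'   (circular mean), `angle_sd_deg`, `n`, `n_excluded`.
#' @export
mean_vector <- function(angles_deg, magnitudes,
                        metric = c("sox9_slope", "edu_centroid")) {
  metric <- match.arg(metric)
  stopifnot(length(angles_deg) == length(magnitudes), length(magnitudes) >= 1,
            all(magnitudes >= 0))
  keep <- !is.na(angles_deg)
  n_excl <- sum(!keep)
  a <- angles_deg[keep] * pi / 180
  mg <- magnitudes[keep]
  if (!length(a)) stop("no vectors with defined angles")
  x <- mg * cos(a); y <- mg * sin(a)
  xb <- mean(x); yb <- mean(y)
  m <- sqrt(xb^2 + yb^2)
  sx <- if (length(x) > 1) sd(x) else 0
  sy <- if (length(y) > 1) sd(y) else 0
  if (m > 0) {
    sd_m <- sqrt(xb^2 * sx^2 + yb^2 * sy^2) / m
    sd_a <- sqrt(yb^2 * sx^2 + xb^2 * sy^2) / m^2 * 180 / pi
    ang <- norm_angle(atan2(yb, xb) * 180 / pi)
  } else {
    sd_m <- sqrt((sx^2 + sy^2) / 2)
    sd_a <- NA_real_
    ang <- NA_real_
  }
  ua <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  # circular SD of the angle sample, degrees
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  csd <- if (R > 0) sqrt(-2 * log(R)) * 180 / pi else NA_real_
  list(angle_deg = ang, magnitude = m, sd_angle_deg = sd_a,
       sd_magnitude = sd_m,
       mag_mean = mean(mg), mag_sd = if (length(mg) > 1) sd(mg) else 0,
       angle_mean_deg = norm_angle(ua), angle_sd_deg = csd,
       n = length(mg), n_excluded = n_excl, metric = metric)
}

#' Fold change between condition mean magnitudes
#'
#' Ratio of a gradient condition's mean polarization magnitude to a baseline
#' (no-gradient) mean, reported to 2 significant figures.
#'
#' @param gradient_mean,baseline_mean condition mean magnitudes; baseline
#'   must be positive.
#' @return fold change, 2 significant figures.
#' @export
condition_ratio <- function(gradient_mean, baseline_mean) {
  if (!is.finite(baseline_mean) || baseline_mean <= 0)
    stop("baseline mean must be positive")
  signif(gradient_mean / baseline_mean, 2)
}

#' Dependence of polarization on channel position
#'
#' Least-squares line and Pearson correlation of colonoid centroid distance
#' from the sink interface against the x-component of the polarization
#' vector (`magnitude * cos(angle)`).
#'
#' @param centroid_x_um positions, um from the sink interface.
#' @param angles_deg,magnitudes polarization vectors.
#' @return list: `slope`, `intercept`, `r`, `p`, `n`, `degenerate` (TRUE when
#'   the position spread is zero).
#' @export
position_dependence <- function(centroid_x_um, angles_deg, magnitudes) {
  xc <- magnitudes * cos(angles_deg * pi / 180)
  ok <- is.finite(centroid_x_um) & is.finite(xc)
  x <- centroid_x_um[ok]; y <- xc[ok]
  if (length(x) < 3) stop("need at least 3 records")
  if (sd(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p = NA_real_, n = length(x), degenerate = TRUE))
  fit <- lm(y ~ x)
  if (sd(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, p = p, n = length(x), degenerate = FALSE)
}

#' Five-number boxplot summary with 5/95 whiskers
#'
#' Mean, median, quartiles and 5th/95th-percentile whiskers (the compass- and
#' box-plot convention used throughout the reporting layer), plus outliers
#' beyond the whiskers.
#'
#' @param values numeric vector.
#' @return list: `mean`, `median`, `q25`, `q75`, `w05`, `w95`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  list(mean = mean(values), median = q[3], q25 = q[2], q75 = q[4],
       w05 = q[1], w95 = q[5],
       outliers = values[values < q[1] | values > q[5]])
}

#' Summarize measured colonoids per condition
#'
#' Aggregates a per-colonoid measurement table ([measure_colonoids()] output
#' plus a `condition` column) into per-condition summaries: counts, mean
#' polarization vectors for both metrics, percent positive per marker, and
#' area / integrated-intensity boxplot summaries.
#'
#' @param records data.frame with a `condition` column.
#' @return data.frame, one row per condition.
#' @export
condition_summary <- function(records) {
  stopifnot("condition" %in% names(records))
  do.call(rbind, lapply(split(records, records$condition), function(d) {
    sx <- if (any(is.finite(d$sox9_magnitude)))
      mean_vector(d$sox9_angle_deg[is.finite(d$sox9_magnitude)],
                  d$sox9_magnitude[is.finite(d$sox9_magnitude)],
                  "sox9_slope") else NULL
    ed <- if (any(is.finite(d$edu_magnitude) & !is.na(d$edu_angle_deg)))
      mean_vector(d$edu_angle_deg, d$edu_magnitude, "edu_centroid") else NULL
    ar <- boxplot_summary(d$area_um2)
    data.frame(condition = d$condition[1], n_colonoids = nrow(d),
               sox9_mag_mean = sx$mag_mean %||% NA_real_,
               sox9_mag_sd = sx$mag_sd %||% NA_real_,
               sox9_angle_mean = sx$angle_mean_deg %||% NA_real_,
               edu_mag_mean = ed$mag_mean %||% NA_real_,
               edu_mag_sd = ed$mag_sd %||% NA_real_,
               edu_angle_mean = ed$angle_mean_deg %||% NA_real_,
               pct_pos_sox9 = 100 * mean(d$pos_sox9, na.rm = TRUE),
               pct_pos_muc2 = 100 * mean(d$pos_muc2, na.rm = TRUE),
               pct_pos_edu = 100 * mean(d$pos_edu, na.rm = TRUE),
               area_median = ar$median, area_q25 = ar$q25, area_q75 = ar$q75)
  }))
}
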