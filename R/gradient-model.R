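#' Fick-model parameters for diffusive gradient entry
#'
#' Parameters of the one-sided diffusion profile
#' `C(x, t) = A + 1/2 * C_O * erfc(x / (2 * sqrt(D * t)))`, where `A` is a
#' free offset (background fluorescence), `C_O` the source concentration and
#' `D` the diffusion coefficient. `x` is measured from the source interface
#' into the Matrigel.
#'
#' @param A baseline offset.
#' @param C_O source concentration (>= 0).
#' @param D diffusion coefficient, m^2/s (> 0).
#' @return a `fick_params` list.
#' @export
fick_params <- function(A = 0, C_O = 1, D = 7.2e-11) {
  stopifnot(is.finite(A), C_O >= 0, D > 0)
  structure(list(A = A, C_O = C_O, D = D), class = "fick_params")
}

#' Complementary-error-function concentration profile
#'
#' Evaluates `A + 1/2 * C_O * erfc(x / (2 * sqrt(D * t)))` on a grid of
#' positions and times.
#'
#' @param params a [fick_params()].
#' @param x_um positions, um from the source interface.
#' @param t_s times, s (> 0).
#' @return a `length(t_s) x length(x_um)` matrix (dropped to a vector when a
#'   single time is given).
#' @export
erfc_profile <- function(params, x_um, t_s) {
  stopifnot(inherits(params, "fick_params"))
  if (any(t_s <= 0)) stop("erfc_profile requires t > 0")
  x_m <- x_um * 1e-6
  out <- t(vapply(t_s, function(tt) {
    params$A + 0.5 * params$C_O * pracma::erfc(x_m / (2 * sqrt(params$D * tt)))
  }, numeric(length(x_um))))
  if (length(t_s) == 1L) drop(out) else out
}

#' Geometry of the source-sink gradient device
#'
#' The Matrigel-filled channel spans `[0, channel_length_um]` with the sink
#' boundary at `x = 0` and the source at the far end. The default reservoir
#' volume is 870x the channel volume (the device's reservoir wells), which is
#' what makes the daily-refresh gradient effectively time-invariant; the
#' 500-uL media volume used in some experiments can be set instead.
#'
#' @param channel_length_um channel length, um.
#' @param channel_volume_ul channel volume, uL.
#' @param reservoir_volume_ul per-reservoir fluid volume, uL.
#' @param refresh_interval_h interval between reservoir refreshes, h.
#' @return a `device_geometry` list.
#' @export
device_geometry <- function(channel_length_um = 1000, channel_volume_ul = 1.5,
                            reservoir_volume_ul = 870 * 1.5,
                            refresh_interval_h = 24) {
  stopifnot(channel_length_um > 0, channel_volume_ul > 0,
            reservoir_volume_ul > 0, refresh_interval_h > 0)
  structure(list(channel_length_um = channel_length_um,
                 channel_volume_ul = channel_volume_ul,
                 reservoir_volume_ul = reservoir_volume_ul,
                 refresh_interval_h = refresh_interval_h),
            class = "device_geometry")
}

#' Assemble a concentration-versus-position-versus-time profile
#'
#' @param x_um position grid, um (from the sink interface for device
#'   simulations; from the source interface for erfc-style entry profiles).
#' @param t_h time points, h.
#' @param conc `length(t_h) x length(x_um)` concentration matrix.
#' @param ... extra fields (e.g. `source_conc`, `geometry`, `mass`).
#' @return a `gradient_profile` list.
#' @export
gradient_profile <- function(x_um, t_h, conc, ...) {
  conc <- rbind(conc)
  stopifnot(nrow(conc) == length(t_h), ncol(conc) == length(x_um),
            all(conc >= -1e-12))
  structure(c(list(x_um = x_um, t_h = t_h, conc = conc), list(...)),
            class = "gradient_profile")
}

#' Simulate gradient formation in the device by 1-D finite volumes
#'
#' Explicit flux-form finite-volume solution of the diffusion equation across
#' the Matrigel channel, coupled to two well-mixed finite reservoirs that
#' exchange flux across half-cell boundary resistances. Reservoir
#' concentrations are reset to their loading values every
#' `refresh_interval_h` (disable with `refresh = FALSE`). The time step is
#' set automatically from the explicit stability limit, so the scheme cannot
#' go unstable silently; mass is conserved exactly between refresh events by
#' the flux form.
#'
#' @param geom a [device_geometry()].
#' @param D diffusion coefficient, m^2/s.
#' @param duration_h simulated time, h.
#' @param source_conc,sink_conc reservoir loading concentrations (arbitrary
#'   units).
#' @param init_conc initial channel concentration; defaults to `sink_conc`.
#' @param n_cells spatial cells across the channel.
#' @param output_dt_h snapshot interval, h.
#' @param refresh logical; refresh reservoirs every `refresh_interval_h`?
#' @param safety fraction of the stability-limited time step to use.
#' @return a [gradient_profile()] with extra fields `sink_res`, `source_res`
#'   (reservoir time series), `mass` (total moles in channel + reservoirs at
#'   each snapshot), `source_conc`, and `geometry`.
#' @export
simulate_device <- function(geom = device_geometry(), D = 7.2e-11,
                            duration_h = 24, source_conc = 1, sink_conc = 0,
                            init_conc = sink_conc, n_cells = 101,
                            output_dt_h = 0.25, refresh = TRUE,
                            safety = 0.8) {
  stopifnot(inherits(geom, "device_geometry"), D > 0, duration_h > 0,
            n_cells >= 3, safety > 0, safety <= 1)
  length_m <- geom$channel_length_um * 1e-6
  area_m2 <- geom$channel_volume_ul * 1e-9 / length_m
  out_t <- seq(0, duration_h, by = output_dt_h) * 3600
  res <- fv_diffuse_cpp(as.integer(n_cells), length_m, area_m2, D,
                        geom$reservoir_volume_ul * 1e-9,
                        source_conc, sink_conc, init_conc,
                        if (refresh) geom$refresh_interval_h * 3600 else 0,
                        out_t, safety)
  gradient_profile(x_um = res$x_um, t_h = out_t / 3600, conc = res$conc,
                   sink_res = res$sink_res, source_res = res$source_res,
                   mass = res$mass, source_conc = source_conc,
                   geometry = geom)
}

#' Temporal concentration variation across the channel
#'
#' For each position, computes `100 * (max - min)` of the concentration over a
#' time window, normalized either by that position's time-mean concentration
#' (`normalize = "position_mean"`) or by the source loading concentration
#' (`normalize = "source"`), and returns the maximum across positions. The
#' source normalization expresses drift as a percentage of the full gradient
#' scale, which is the natural stability measure for a linear gradient whose
#' concentrations near the sink approach zero.
#'
#' @param profile a [gradient_profile()].
#' @param window `c(t0, t1)` assessment window, h.
#' @param normalize `"position_mean"` or `"source"`.
#' @return maximum percent variation across positions; per-position values in
#'   attribute `"per_position"`.
#' @export
gradient_variation <- function(profile, window = range(profile$t_h),
                               normalize = c("position_mean", "source")) {
  stopifnot(inherits(profile, "gradient_profile"))
  normalize <- match.arg(normalize)
  sel <- profile$t_h >= window[1] - 1e-9 & profile$t_h <= window[2] + 1e-9
  if (!any(sel)) stop("assessment window outside the simulated duration")
  C <- profile$conc[sel, , drop = FALSE]
  rng <- apply(C, 2, function(v) diff(range(v)))
  if (normalize == "position_mean") {
    mu <- colMeans(C)
    zero <- mu <= .Machine$double.eps
    if (any(zero)) {
      warning(sum(zero), " zero-mean position(s) excluded from variation")
      rng <- rng[!zero]; mu <- mu[!zero]
    }
    per_pos <- 100 * rng / mu
  } else {
    src <- profile$source_conc
    if (is.null(src) || src <= 0) stop("source normalization needs source_conc > 0")
    per_pos <- 100 * rng / src
  }
  structure(max(per_pos), per_position = per_pos)
}

#' Fit the erfc entry profile to concentration data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `C = A + 1/2 * C_O * erfc(x / (2 * sqrt(D * t)))` over all position/time
#' samples of a profile, returning the fitted [fick_params()] with the
#' standard error of `D`. Positions are taken as measured from the source
#' interface. Time-constant profiles are flagged non-identifiable rather than
#' fitted; non-convergence is flagged, never silent.
#'
#' @param profile a [gradient_profile()] with at least 2 time points and 10
#'   positions.
#' @param start optional named list of starting values (`A`, `C_O`, `D`).
#' @param fix optional named list pinning parameters at fixed values.
#' @return a `fick_fit` list: `params` ([fick_params()] or NULL), `se_D`,
#'   `converged`, `identifiable`, and the underlying `fit` object.
#' @export
fit_diffusion_coefficient <- function(profile, start = NULL, fix = list()) {
  stopifnot(inherits(profile, "gradient_profile"))
  if (length(profile$t_h) < 2 || length(profile$x_um) < 10)
    stop("need >= 2 time points and >= 10 positions")
  d <- data.frame(x = rep(profile$x_um * 1e-6, each = length(profile$t_h)),
                  t = rep(profile$t_h * 3600, times = length(profile$x_um)),
                  C = as.vector(profile$conc))
  # identifiability pre-check: D only enters through temporal evolution
  tvar <- apply(profile$conc, 2, function(v) diff(range(v)))
  scale <- max(abs(d$C), 1e-300)
  if (max(tvar) / scale < 1e-10)
    return(structure(list(params = NULL, se_D = NA_real_, converged = FALSE,
                          identifiable = FALSE, fit = NULL),
                     class = "fick_fit"))
  if (is.null(start))
    start <- list(A = min(d$C), C_O = 2 * (max(d$C) - min(d$C)), D = 1e-10)
  start[names(fix)] <- NULL
  form <- C ~ A + 0.5 * C_O * pracma::erfc(x / (2 * sqrt(D * t)))
  if (length(fix)) {
    env <- list2env(fix, parent = environment())
    environment(form) <- env
  }
  lower <- c(A = -Inf, C_O = 0, D = 1e-16)[names(start)]
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(params = NULL, se_D = NA_real_, converged = FALSE,
                          identifiable = TRUE, fit = fit),
                     class = "fick_fit"))
  est <- as.list(coef(fit))
  est[names(fix)] <- fix
  se_D <- if ("D" %in% names(coef(fit)))
    summary(fit)$coefficients["D", "Std. Error"] else NA_real_
  structure(list(params = fick_params(A = est$A, C_O = est$C_O, D = est$D),
                 se_D = se_D, converged = fit$convInfo$isConv %||% TRUE,
                 identifiable = TRUE, fit = fit),
            class = "fick_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fick_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("<fick_fit> non-identifiable (no temporal evolution)\n")
  } else if (is.null(x$params)) {
    cat("<fick_fit> did not converge\n")
  } else {
    cat(sprintf("<fick_fit> D = %.3e +/- %.1e m^2/s, A = %.3g, C_O = %.3g%s\n",
                x$params$D, x$se_D, x$params$A, x$params$C_O,
                if (isTRUE(x$converged)) "" else " (NOT converged)"))
  }
  invisible(x)
}

#' Write a gradient profile as long-format CSV
#'
#' Columns `t_h, x_um, conc`.
#'
#' @param profile a [gradient_profile()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_gradient_csv <- function(profile, path) {
  d <- data.frame(t_h = rep(profile$t_h, times = length(profile$x_um)),
                  x_um = rep(profile$x_um, each = length(profile$t_h)),
                  conc = as.vector(profile$conc))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
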