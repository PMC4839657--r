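# shared fixtures and independent oracles (kept free of package internals)

as_plain_mat <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

disk_mask <- function(n, center = c((n + 1) / 2, (n + 1) / 2), radius) {
  rr <- matrix(rep(seq_len(n), times = n), n, n)
  cc <- matrix(rep(seq_len(n), each = n), n, n)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

rect_mask <- function(nr, nc, r0, c0, h, w) {
  m <- matrix(FALSE, nr, nc)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

# one-colonoid scene with stated true polarization; body area matches the
# reported median colonoid area (~13,100 um^2)
one_colonoid_spec <- function(seed, egfp_slope = 0.01, egfp_angle = 40,
                              edu_offset = 0.25, edu_angle = 0,
                              shape = c(220, 220),
                              noise = list(poisson_scale = 1, gaussian_sd = 2)) {
  scene_spec(
    image_shape = shape, pixel_size = 1,
    colonoids = list(colonoid_spec(
      center = shape / 2, semi_axes = c(72, 58), orientation = 20,
      egfp_base = 0.6, egfp_slope = egfp_slope, egfp_angle = egfp_angle,
      n_edu_puncta = 35, edu_centroid_offset_frac = edu_offset,
      edu_angle = edu_angle, muc2_fraction = 0.15)),
    noise = noise, rng_seed = seed)
}

# brute-force minimum-cross-entropy threshold: scan midpoints between all
# sorted unique pixel values, evaluating the objective directly per pixel
brute_li_threshold <- function(v) {
  u <- sort(unique(v))
  cand <- (u[-1] + u[-length(u)]) / 2
  obj <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    m1 <- mean(lo); m2 <- mean(hi)
    s <- 0
    if (length(lo) && m1 > 0) s <- s + sum(lo) * log(m1)
    if (length(hi) && m2 > 0) s <- s + sum(hi) * log(m2)
    -s
  }, numeric(1))
  cand[which.min(obj)]
}

# brute-force Holm-Sidak step-down: largest k such that rejecting the k
# smallest p-values is consistent with every Sidak bound
brute_holm_sidak <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  crit <- sapply(seq_len(m), function(i) 1 - (1 - alpha)^(1 / (m - i + 1)))
  best_k <- 0
  for (k in m:0) {
    ok <- TRUE
    if (k > 0 && any(ps[1:k] > crit[1:k])) ok <- FALSE
    if (k < m && ps[k + 1] <= crit[k + 1]) ok <- FALSE
    if (ok) { best_k <- k; break }
  }
  rej <- logical(m)
  if (best_k > 0) rej[ord[1:best_k]] <- TRUE
  rej
}

# dense matrix-exponential propagator for the channel + reservoir ODE system,
# an independent oracle for the finite-volume stepper (no refresh events)
expm_device_profile <- function(geom, D, t_h, source_conc = 1, sink_conc = 0,
                                init_conc = sink_conc, n_cells = 21) {
  L <- geom$channel_length_um * 1e-6
  A <- geom$channel_volume_ul * 1e-9 / L
  Vr <- geom$reservoir_volume_ul * 1e-9
  dx <- L / n_cells
  Vc <- A * dx
  kI <- D * A / dx
  kB <- D * A / (dx / 2)
  n <- n_cells + 2                 # state: sink, cells..., source
  M <- matrix(0, n, n)
  vol <- c(Vr, rep(Vc, n_cells), Vr)
  link <- function(i, j, k) {      # conductance k between compartments i, j
    M[i, i] <<- M[i, i] - k / vol[i]; M[i, j] <<- M[i, j] + k / vol[i]
    M[j, j] <<- M[j, j] - k / vol[j]; M[j, i] <<- M[j, i] + k / vol[j]
  }
  link(1, 2, kB)
  for (i in 2:(n_cells)) link(i, i + 1, kI)
  link(n_cells + 1, n_cells + 2, kB)
  C0 <- c(sink_conc, rep(init_conc, n_cells), source_conc)
  E <- Matrix::expm(M * t_h * 3600)
  as.numeric(E %*% C0)
}
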