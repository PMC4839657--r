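test_that("ratio image divides inside the mask and floors weak denominators", {
  m <- rect_mask(20, 20, 5, 5, 10, 10)
  den <- matrix(50, 20, 20)
  r1 <- ratio_image(den, den, m)
  expect_equal(unique(r1[m]), 1)
  expect_equal(unique(r1[!m]), 0)
  r2 <- ratio_image(2 * den, den, m)
  expect_equal(unique(r2[m]), 2)
  # zeroed denominator pixels are excluded and counted
  den0 <- den
  den0[5, 5:9] <- 0
  expect_message(r3 <- ratio_image(den, den0, m), "5 pixel")
  expect_equal(attr(r3, "n_excluded"), 5)
  expect_equal(unique(r3[5, 5:9]), 0)
  expect_error(ratio_image(den, matrix(0, 20, 20), m), "zero everywhere")
})

test_that("centre slice profile averages the stated physical band", {
  m <- rect_mask(40, 40, 6, 6, 30, 30)
  # constant image: constant profile over the columns under the mask
  pc <- center_slice_profile(matrix(7, 40, 40), m, 20, pixel_size = 1)
  expect_equal(unique(pc$intensity), 7)
  expect_equal(nrow(pc), 30)
  # ramp in x passes through: intensity equals the column position
  ramp <- matrix(rep(seq_len(40), each = 40), 40, 40)
  pr <- center_slice_profile(ramp, m, 20, pixel_size = 1)
  expect_equal(pr$intensity, pr$x_um + 0.5)
  # a 20-um band at 2 um/px covers exactly 10 rows: a row-index image
  # averages to the mean of those 10 row indices
  rows <- matrix(rep(seq_len(40), times = 40), 40, 40)
  pb <- center_slice_profile(rows, m, 20, pixel_size = 2)
  # mask rows 6..35, centre 20.5, 10-row band = rows 16..25
  expect_equal(unique(pb$intensity), mean(16:25))
})

test_that("rotation-slope metric recovers direction and magnitude of a planar ramp", {
  # analytic disk with a known in-mask ratio gradient, no generator involved
  n <- 101
  m <- disk_mask(n, radius = 40)
  cc <- matrix(rep(seq_len(n), each = n), n, n)
  rr <- matrix(rep(seq_len(n), times = n), n, n)
  x <- cc - 51; y <- -(rr - 51)
  for (ang in c(0, 40, 138, 250)) {
    a <- ang * pi / 180
    img <- 0.6 + 0.01 * (x * cos(a) + y * sin(a))
    img[!m] <- 0
    v <- sox9_polarization(img, m, pixel_size = 1)
    dang <- abs(((v$angle_deg - ang + 180) %% 360) - 180)
    expect_lt(dang, 2)
    expect_lt(abs(v$magnitude - 0.01) / 0.01, 0.05)
  }
  # constant ratio: unpolarized, magnitude below 1e-4
  flat <- matrix(0, n, n); flat[m] <- 0.6
  expect_lt(sox9_polarization(flat, m, 1)$magnitude, 1e-4)
})

test_that("rotation-slope magnitude is invariant to common channel scaling", {
  sp <- one_colonoid_spec(13, egfp_angle = 75)
  sc <- make_scene(sp)
  m <- sc$truth$label_map == 1
  egfp <- as_plain_mat(sc$clean$egfp); dsred <- as_plain_mat(sc$clean$dsred)
  v1 <- sox9_polarization(suppressMessages(ratio_image(egfp, dsred, m)), m, 1)
  v2 <- sox9_polarization(
    suppressMessages(ratio_image(7.3 * egfp, 7.3 * dsred, m)), m, 1)
  expect_equal(v1$magnitude, v2$magnitude, tolerance = 1e-10)
  expect_equal(v1$angle_deg, v2$angle_deg)
})

test_that("rotating the scene rotates the recovered angle", {
  sp <- one_colonoid_spec(19, egfp_angle = 20)
  sc <- make_scene(sp)
  m <- sc$truth$label_map == 1
  r <- suppressMessages(ratio_image(as_plain_mat(sc$clean$egfp),
                                    as_plain_mat(sc$clean$dsred), m))
  v0 <- sox9_polarization(r, m, 1)
  r30 <- rotate_nn(unclass(r), 30)
  m30 <- rotate_nn(m * 1, 30) > 0.5
  v30 <- sox9_polarization(r30, m30, 1)
  shift <- ((v30$angle_deg - v0$angle_deg) %% 360)
  expect_lt(abs(shift - 30), 3)
})

test_that("centroid-offset metric matches closed-form single-column placements", {
  # rectangle of N columns with all EdU in the last column: (N-1)/(2N)
  N <- 100
  m <- rect_mask(40, 120, 11, 11, 20, N)
  hoechst <- matrix(100, 40, 120)
  edu <- matrix(0, 40, 120)
  edu[11:30, 10 + N] <- 50
  v <- edu_polarization(edu, hoechst, m, 1)
  expect_equal(v$magnitude, (N - 1) / (2 * N), tolerance = 1e-12)
  expect_equal(v$angle_deg, 0)
  # EdU proportional to Hoechst everywhere: centroids coincide
  v0 <- edu_polarization(3 * hoechst, hoechst, m, 1)
  expect_equal(v0$magnitude, 0)
  expect_true(isTRUE(attr(v0, "undefined")) || v0$magnitude == 0)
  # zero EdU: flagged undefined
  vz <- edu_polarization(matrix(0, 40, 120), hoechst, m, 1)
  expect_true(attr(vz, "undefined"))
  expect_true(is.na(vz$angle_deg))
})

test_that("centroid-offset magnitude never exceeds 0.5 on symmetric masks", {
  m <- rect_mask(30, 70, 6, 6, 20, 60)
  hoechst <- matrix(100, 30, 70)
  mags <- withr::with_seed(99, vapply(1:400, function(i) {
    edu <- matrix(0, 30, 70)
    k <- sample(3:40, 1)
    px <- which(m)
    edu[sample(px, k)] <- runif(k, 1, 100)
    edu_polarization(edu, hoechst, m, 1)$magnitude
  }, numeric(1)))
  expect_true(all(mags <= 0.5))
})

test_that("positivity applies the fraction rule with ties counting positive", {
  m <- rect_mask(20, 20, 1, 1, 10, 10)     # 100 px
  img <- matrix(0, 20, 20)
  img[m][1:30] <- 10
  expect_true(positivity(img, m, 5, 0.25))     # 30% positive
  img2 <- matrix(0, 20, 20)
  img2[m][1:10] <- 10
  expect_true(positivity(img2, m, 5, 0.10))    # exactly 10%: positive
  expect_false(positivity(img2, m, 5, 0.25))
  expect_false(positivity(matrix(0, 20, 20), m, 5, 0.10))
  # threshold calibration: quantile of out-of-object pixels
  withr::with_seed(1, bgimg <- matrix(rnorm(400, 10, 1), 20, 20))
  thr <- calibrate_positivity_threshold(bgimg, m, prob = 0.99)
  expect_equal(thr, quantile(bgimg[!m], 0.99, names = FALSE))
})

test_that("measure_colonoids yields one consistent record per label", {
  sp <- random_scene_spec(55, n_colonoids = 2, image_shape = c(300, 300),
                          egfp_slope = 0.01, edu_offset = 0.25)
  sc <- make_scene(sp)
  rec <- suppressMessages(measure_colonoids(sc$channels, sc$truth$label_map))
  expect_equal(nrow(rec), 2)
  expect_equal(rec$label, 1:2)
  tab <- sc$truth$table
  expect_equal(rec$area_um2, tab$area_um2, tolerance = 0.05)
  expect_true(all(rec$pos_sox9))
  expect_true(all(is.finite(rec$sox9_magnitude)))
  # centroid x is measured from the left (sink) edge in um
  expect_true(all(rec$centroid_x_um > 0 & rec$centroid_x_um < 300))
  # empty label map: empty table
  empty <- suppressMessages(
    measure_colonoids(sc$channels, pixel_grid(matrix(0L, 50, 50))))
  expect_equal(nrow(empty), 0)
})

test_that("missing channels degrade to NA fields without failing", {
  sp <- one_colonoid_spec(23)
  sc <- make_scene(sp)
  chans <- sc$channels[c("dsred", "egfp")]
  expect_message(rec <- measure_colonoids(chans, sc$truth$label_map),
                 "missing channel")
  expect_equal(nrow(rec), 1)
  expect_true(is.na(rec$edu_magnitude))
  expect_true(is.na(rec$int_hoechst))
  expect_true(is.na(rec$pos_edu))
  expect_true(is.finite(rec$sox9_magnitude))
})
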