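test_that("top-hat removes flat background and ramps but keeps small objects", {
  # constant image maps to zero
  flat <- pixel_grid(matrix(37, 60, 60))
  expect_equal(max(abs(tophat_filter(flat, radius_um = 10))), 0)
  # bright disk smaller than the element survives, background vanishes;
  # oracle: direct erosion/dilation morphology on a toy grid
  img <- matrix(10, 50, 50)
  d <- disk_mask(50, c(25, 25), 5)
  img[d] <- 110
  th <- tophat_filter(pixel_grid(img), radius_um = 10)
  expect_equal(mean(th[d]), 100, tolerance = 0.02)
  expect_equal(max(th[!d]), 0)
  # linear illumination ramp is removed when the element exceeds the object
  ramp <- matrix(rep(seq(0, 20, length.out = 50), each = 50), 50, 50)
  th_ramp <- tophat_filter(pixel_grid(img + ramp), radius_um = 10)
  expect_lt(max(abs(th_ramp[d] - th[d])), 3)
  expect_error(tophat_filter(pixel_grid(img, pixel_size = 20), radius_um = 10),
               "1 px")
})

test_that("global constants do not change the segmentation", {
  sp <- one_colonoid_spec(17, shape = c(160, 160))
  sc <- make_scene(sp)
  base <- segment_colonoids(sc$channels$dsred, sc$channels$brightfield)
  shifted <- segment_colonoids(pixel_grid(as_plain_mat(sc$channels$dsred) + 50),
                               sc$channels$brightfield)
  expect_identical(as.integer(base), as.integer(shifted))
})

test_that("minimum cross-entropy threshold matches a brute-force oracle", {
  # two-valued image: threshold strictly between the values
  two <- matrix(rep(c(10, 200), c(70, 30)), 10, 10)
  mask <- threshold_min_cross_entropy(two)
  thr <- attr(mask, "threshold")
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_identical(unclass(mask)[two == 200][1], TRUE)
  # bimodal Gaussian mixture: < 1% misclassification against the labels,
  # and agreement with an exhaustive per-pixel objective scan
  withr::with_seed(42, {
    lab <- runif(4000) < 0.5
    v <- ifelse(lab, rnorm(4000, 180, 10), rnorm(4000, 50, 10))
  })
  img <- matrix(v, 50, 80)
  got <- threshold_min_cross_entropy(img)
  expect_lt(mean(c(got) != matrix(lab, 50, 80)), 0.01)
  thr_oracle <- brute_li_threshold(v)
  expect_lt(mean(c(got) != c(img > thr_oracle)), 0.005)
  # polarity contract: inverting the image segments the complement
  inv <- threshold_min_cross_entropy(max(img) - img)
  expect_lt(mean(c(inv) == c(got)), 0.01)
  expect_error(threshold_min_cross_entropy(matrix(5, 4, 4)), "constant")
})

test_that("mask cleaning fills holes and applies the strict area rule", {
  # annulus of ~1500 um^2 becomes a solid disk
  ann <- disk_mask(60, radius = 24) & !disk_mask(60, radius = 12)
  cleaned <- clean_mask(ann, 1000, pixel_size = 1)
  expect_true(all(cleaned[disk_mask(60, radius = 23)]))
  # exactly 1000 um^2 is kept; 999 is removed
  at_rule <- rect_mask(60, 60, 10, 10, 25, 40)    # 1000 px
  expect_equal(sum(clean_mask(at_rule, 1000, 1)), 1000)
  below <- rect_mask(60, 60, 10, 10, 27, 37)      # 999 px
  expect_equal(sum(clean_mask(below, 1000, 1)), 0)
  # physical units: the same 1000-px object at 2 um/px is 4000 um^2
  expect_equal(sum(clean_mask(at_rule, 3999, pixel_size = 2)), 1000)
})

test_that("Chan-Vese refinement converges, grows to brightfield support, and flags degeneracy", {
  # fixed point: boundary coincides with initialization
  obj <- disk_mask(80, radius = 20)
  bf <- matrix(230, 80, 80); bf[obj] <- 150
  out <- chan_vese_refine(bf, obj)
  expect_true(attr(out, "converged"))
  iou <- sum(out & obj) / sum(out | obj)
  expect_gt(iou, 0.95)
  # initialization 30% smaller than the true object grows to the boundary
  small <- disk_mask(80, radius = 14)
  grown <- chan_vese_refine(bf, small)
  iou2 <- sum(grown & obj) / sum(grown | obj)
  expect_gt(iou2, 0.95)
  # uniform brightfield: degenerate energy, initialization returned
  expect_warning(res <- chan_vese_refine(matrix(100, 80, 80), obj),
                 "degenerate")
  expect_identical(unclass(res)[, ], obj)
  expect_false(attr(res, "converged"))
})

test_that("debris and border objects are removed by the 20% brightfield rule", {
  fl <- matrix(0L, 60, 90)
  bf <- matrix(0L, 60, 90)
  # object 1: identical footprints -> kept
  fl[rect_mask(60, 90, 10, 5, 20, 20)] <- 1L
  bf[rect_mask(60, 90, 10, 5, 20, 20)] <- 1L
  # object 2: brightfield 25% larger -> debris, removed
  fl[rect_mask(60, 90, 10, 35, 20, 20)] <- 2L
  bf[rect_mask(60, 90, 8, 33, 20, 25)] <- 2L
  # object 3: no brightfield match -> kept, reported
  fl[rect_mask(60, 90, 40, 60, 15, 15)] <- 3L
  out <- remove_debris(fl, bf)
  expect_equal(attr(out, "removed_debris"), 2L)
  expect_equal(attr(out, "unmatched"), 3L)
  expect_equal(sort(unique(c(out))), c(0L, 1L, 2L))   # relabeled 1..2
  expect_equal(unique(out[fl == 1L]), 1L)
  expect_equal(unique(out[fl == 2L]), 0L)
  # border-touching objects are removed
  fl2 <- matrix(0L, 40, 40)
  fl2[rect_mask(40, 40, 1, 10, 10, 10)] <- 1L
  fl2[rect_mask(40, 40, 20, 10, 10, 10)] <- 2L
  out2 <- remove_debris(fl2, fl2)
  expect_equal(attr(out2, "removed_border"), 1L)
  expect_equal(unique(out2[fl2 == 1L]), 0L)
  expect_equal(unique(out2[fl2 == 2L]), 1L)
  # perimeter comparison mode: a 20x30 brightfield box against a 20x20
  # fluorescence box is 26% longer in perimeter -> removed
  bf_p <- matrix(0L, 60, 90)
  bf_p[rect_mask(60, 90, 10, 5, 20, 20)] <- 1L
  bf_p[rect_mask(60, 90, 8, 33, 20, 30)] <- 2L
  out3 <- remove_debris(fl, bf_p, compare = "perimeter")
  expect_equal(attr(out3, "removed_debris"), 2L)
})

test_that("full pipeline segments synthetic scenes and drops only debris", {
  sp <- random_scene_spec(42, n_colonoids = 3, n_debris = 2)
  sc <- make_scene(sp)
  lab <- segment_colonoids(sc$channels$dsred, sc$channels$brightfield)
  expect_equal(max(lab), 3)
  for (i in 1:3) {
    tm <- sc$truth$label_map == i
    ov <- lab[tm]; ov <- ov[ov > 0]
    expect_gt(length(ov), 0)
    j <- as.integer(names(which.max(table(ov))))
    iou <- sum(tm & lab == j) / sum(tm | lab == j)
    expect_gt(iou, 0.8)
  }
  expect_equal(setdiff(unique(lab[sc$truth$debris_fluor > 0]), 0L), integer(0))
  # retained-object guarantees: area, holes, border
  ps <- px_size(lab)
  for (j in seq_len(max(lab))) {
    m <- lab == j
    expect_gte(sum(m) * ps^2, 1000)
    filled <- clean_mask(m, 0, ps)
    expect_equal(sum(filled), sum(m))     # no interior holes
    expect_false(any(m[1, ] | m[nrow(m), ] | m[, 1] | m[, ncol(m)]))
  }
})

test_that("degenerate inputs give valid empty segmentations", {
  withr::with_seed(8, blank <- matrix(abs(rnorm(160 * 160, 20, 2)), 160, 160))
  expect_message(lab <- segment_colonoids(pixel_grid(blank), NULL), "empty")
  expect_equal(max(lab), 0)
  # one object well below the 1000-um^2 rule
  sp <- scene_spec(image_shape = c(160, 160),
                   colonoids = list(colonoid_spec(c(80, 80), c(14, 11))),
                   rng_seed = 2)
  sc <- make_scene(sp)
  expect_equal(sum(sc$truth$label_map > 0) < 1000, TRUE)
  expect_message(lab2 <- segment_colonoids(sc$channels$dsred,
                                           sc$channels$brightfield), "empty")
  expect_equal(max(lab2), 0)
})
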