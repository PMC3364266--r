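test_that("temporal unwrapping corrects aliased sequences", {
  # stored [80, -70, 90] at venc 100 is the wrap of true [80, 130, 90]
  ph <- array(c(80, -70, 90), c(1, 1, 3))
  ser <- velocity_series(ph, ph * 0 + 1, 100, c(1, 1), c(0, 30, 60),
                         "arterial")
  out <- unwrap_velocity(ser)
  expect_equal(as.vector(out$phase), c(80, 130, 90))
})

test_that("unwrapping leaves smooth sequences unchanged and is idempotent", {
  set.seed(4)
  v <- 40 * sin(2 * pi * (0:23) / 24)          # |v| < venc/2, smooth
  ph <- array(rep(v, each = 4), c(2, 2, 24))
  ser <- velocity_series(ph, ph * 0 + 1, 100, c(1, 1), seq(0, 23) * 30,
                         "arterial")
  expect_equal(unwrap_velocity(ser)$phase, ph)
  const <- velocity_series(array(7, c(2, 2, 5)), array(1, c(2, 2, 5)),
                           100, c(1, 1), (0:4) * 30, "arterial")
  expect_equal(unwrap_velocity(const)$phase, const$phase)

  wrapped <- velocity_series(array(c(80, -70, 90, -95), c(1, 1, 4)),
                             array(1, c(1, 1, 4)), 100, c(1, 1),
                             (0:3) * 30, "arterial")
  once <- unwrap_velocity(wrapped)
  expect_equal(unwrap_velocity(once)$phase, once$phase)
})

test_that("otsu threshold separates two classes exactly", {
  img <- c(rep(0, 50), rep(10, 50))
  thr <- otsu_threshold(img)
  expect_true(all(img[img <= thr] == 0))
  expect_true(all(img[img > thr] == 10))
  expect_error(otsu_threshold(rep(3, 100)), "degenerate")
})

test_that("otsu equals the brute-force between-class variance sweep", {
  brute_otsu <- function(x) {
    nbin <- 256L
    edges <- seq(min(x), max(x), length.out = nbin + 1L)
    h <- tabulate(pmin(findInterval(x, edges), nbin), nbin)
    mids <- (edges[-1] + edges[-(nbin + 1)]) / 2
    bc <- rep(-Inf, nbin - 1)
    for (k in 1:(nbin - 1)) {
      w0 <- sum(h[1:k]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(h[1:k] * mids[1:k]) / w0
      m1 <- sum(h[(k + 1):nbin] * mids[(k + 1):nbin]) / w1
      bc[k] <- w0 * w1 * (m0 - m1)^2
    }
    plateau <- which(bc >= max(bc) * (1 - 1e-12))
    edges[plateau[ceiling(length(plateau) / 2)] + 1L]
  }
  set.seed(9)
  for (i in 1:10) {
    x <- c(rnorm(500, 0, runif(1, 1, 10)), rnorm(500, runif(1, 30, 100), 5))
    expect_equal(otsu_threshold(x), brute_otsu(x), tolerance = 1e-12)
  }
  # bimodal Gaussians at 0 and 100: threshold lands between the modes
  x <- c(rnorm(5000, 0, 5), rnorm(5000, 100, 5))
  thr <- otsu_threshold(x)
  expect_gt(thr, 25); expect_lt(thr, 75)
})

test_that("segmentation recovers a bright disk", {
  ser <- disk_series(radius = 5)
  mask <- segment_compartment(ser, square_roi(3, 20), "single_frame")
  area <- sum(mask$mask[, , 1])
  expect_lt(abs(area - pi * 25) / (pi * 25), 0.10)
  expect_error(segment_compartment(ser, square_roi(0, 2), "single_frame"))
})

test_that("per-frame segmentation tracks an oscillating radius", {
  n_frames <- 24
  radii <- round(5 + sin(2 * pi * (0:(n_frames - 1)) / n_frames))  # 4..6
  ser <- disk_series(radius = radii, n_frames = n_frames, compartment = "arterial")
  mask <- segment_compartment(ser, square_roi(3, 20), "per_frame")
  for (i in seq_len(n_frames)) {
    true_area <- sum(outer((0:23) - 11.5, (0:23) - 11.5,
                           function(x, y) x^2 + y^2) <= radii[i]^2)
    got <- sum(mask$mask[, , i])
    ring <- sum(outer((0:23) - 11.5, (0:23) - 11.5, function(x, y)
      x^2 + y^2 <= (radii[i] + 2)^2 & x^2 + y^2 > (radii[i] - 2)^2))
    expect_lte(abs(got - true_area), ring)
  }
})

test_that("frequency segmentation finds exactly the pulsatile voxels", {
  set.seed(21)
  n <- 20; n_frames <- 24
  ph <- array(rnorm(n * n * n_frames, 0, 0.3), c(n, n, n_frames))
  truth <- matrix(FALSE, n, n)
  truth[9:12, 9:12] <- TRUE
  for (i in seq_len(n_frames))
    ph[, , i][truth] <- ph[, , i][truth] +
      3 * sin(2 * pi * (i - 1) / n_frames)
  ser <- velocity_series(ph, ph * 0 + 1, 12, c(0.8, 0.7),
                         seq(0, by = 35, length.out = n_frames), "spinal")
  mask <- segment_spinal_frequency(ser, square_roi(4, 16))
  expect_equal(mask$mask[, , 1], truth)

  # doubling the pulsatile amplitude leaves the mask unchanged
  ph2 <- ph
  for (i in seq_len(n_frames))
    ph2[, , i][truth] <- ph2[, , i][truth] +
      3 * sin(2 * pi * (i - 1) / n_frames)
  ser2 <- velocity_series(ph2, ph2 * 0 + 1, 12, c(0.8, 0.7),
                          seq(0, by = 35, length.out = n_frames), "spinal")
  expect_equal(segment_spinal_frequency(ser2, square_roi(4, 16))$mask,
               mask$mask)
})

test_that("all-static ROI fails frequency segmentation", {
  ph <- array(0, c(12, 12, 10))
  ser <- velocity_series(ph, ph + 1, 12, c(1, 1), (0:9) * 50, "spinal")
  expect_error(segment_spinal_frequency(ser, square_roi(2, 9)))
})

test_that("rim check passes true masks and flags eroded ones", {
  ser <- disk_series(radius = 6, value = 5)
  truth <- segment_compartment(ser, square_roi(3, 20), "single_frame")
  rep_ok <- rim_check(ser, truth, noise_sd_cm_s = 0.1)
  expect_true(all(rep_ok$pass))

  eroded <- truth
  eroded$mask[, , 1] <- csfpulse:::erode1(truth$mask[, , 1])
  rep_bad <- rim_check(ser, eroded, noise_sd_cm_s = 0.1)
  expect_false(any(rep_bad$pass))
  expect_equal(rep_bad$suggestion[1], "grow")

  tiny <- truth
  m <- truth$mask[, , 1] & FALSE; m[12, 12] <- TRUE
  tiny$mask <- array(m, dim(truth$mask))
  expect_error(rim_check(ser, tiny), "inner rim")
})

test_that("background correction is exactly linear", {
  ser <- disk_series(radius = 4, value = 6)
  mask <- segment_compartment(ser, square_roi(3, 20), "single_frame")
  shifted <- ser
  shifted$phase <- ser$phase + 1.25
  corr <- correct_background(shifted, mask, "rectangle", c(0, 3, 0, 3))
  expect_equal(corr$phase, ser$phase, tolerance = 1e-12)
  expect_equal(attr(corr, "background_offset_cm_s"), 1.25)

  corr0 <- correct_background(ser, mask, "rectangle", c(0, 3, 0, 3))
  expect_equal(corr0$phase, ser$phase, tolerance = 1e-12)

  expect_error(correct_background(ser, mask, "rectangle", c(8, 16, 8, 16)),
               "overlaps")
})

test_that("flow integration is the area-velocity sum", {
  ph <- array(0, c(3, 3, 2))
  ph[1:3, 1, 1] <- c(1, 2, 3)      # cm/s = 10,20,30 mm/s over 1 mm^2 pixels
  ser <- velocity_series(ph, ph + 1, 100, c(1, 1), c(0, 500), "aqueduct")
  m <- array(FALSE, c(3, 3, 1)); m[1:3, 1, 1] <- TRUE
  mask <- structure(list(mask = m, per_frame = FALSE, compartment = "aqueduct"),
                    class = "segmentation_mask")
  w <- compute_flow(ser, mask, 1000)
  expect_equal(w$flow, c(0.06, 0))
})

test_that("flow integration is additive over disjoint masks", {
  set.seed(31)
  ph <- array(rnorm(64 * 4), c(8, 8, 4))
  ser <- velocity_series(ph, ph * 0 + 1, 100, c(0.8, 0.7), (0:3) * 100,
                         "arterial")
  mk <- function(sel) structure(list(mask = array(sel, c(8, 8, 1)),
                                     per_frame = FALSE, compartment = "arterial"),
                                class = "segmentation_mask")
  a <- matrix(FALSE, 8, 8); a[1:4, ] <- TRUE
  b <- matrix(FALSE, 8, 8); b[5:8, ] <- TRUE
  expect_equal(compute_flow(ser, mk(a), 400)$flow +
                 compute_flow(ser, mk(b), 400)$flow,
               compute_flow(ser, mk(a | b), 400)$flow, tolerance = 1e-12)
})

test_that("masks are invariant to affine magnitude rescaling", {
  ser <- disk_series(radius = 5)
  m1 <- segment_compartment(ser, square_roi(3, 20), "single_frame")
  ser2 <- ser
  ser2$magnitude <- ser$magnitude * 3.7 + 12
  m2 <- segment_compartment(ser2, square_roi(3, 20), "single_frame")
  expect_equal(m1$mask, m2$mask)
})
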