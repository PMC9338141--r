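test_that("transfer functions validate and interpolate piecewise-linearly", {
  expect_error(transfer_function(c(0, 0), 1, 0, 0, 1), "increasing")
  expect_error(transfer_function(c(0, 1), 1, 0, 0, c(0, 2)), "opacity")
  tf <- transfer_function(c(0, 10, 20), r = 1, g = 0, b = 0,
                          alpha = c(1, 0.5, 0))
  out <- tf_eval(tf, c(-5, 0, 5, 15, 25))
  expect_equal(out[, "alpha"], c(1, 1, 0.75, 0.25, 0))  # clamped ends
  expect_equal(out[, "r"], rep(1, 5))
})

test_that("default transfer functions realize the colour scheme", {
  tfs <- default_transfer_functions(1000)
  iv <- seq(0, 1000, by = 50)
  # sub-volume 4 (label 0) is completely transparent
  expect_true(all(tf_eval(tfs[["0"]], iv)[, "alpha"] == 0))
  # nerves are yellow: red ~ green >> blue
  y <- tf_eval(tfs[["3"]], 500)
  expect_gt(y[, "r"], 0.9)
  expect_gt(y[, "g"], 0.8)
  expect_lt(y[, "b"], 0.2)
  # vessel opacity is non-increasing with intensity and zero at CSF-bright
  a <- tf_eval(tfs[["1"]], iv)[, "alpha"]
  expect_true(all(diff(a) <= 1e-12))
  expect_equal(a[length(a)], 0)
  # brainstem is light gray at moderate opacity
  g <- tf_eval(tfs[["2"]], 500)
  expect_equal(unname(g[, "r"]), unname(g[, "g"]))
  expect_true(g[, "alpha"] > 0 && g[, "alpha"] < 0.5)
})

test_that("transfer functions round-trip through YAML", {
  tfs <- default_transfer_functions(1200)
  f <- tempfile(fileext = ".yaml")
  write_transfer_functions(tfs, f)
  tfs2 <- read_transfer_functions(f)
  for (lc in names(tfs))
    expect_equal(as.data.frame(tfs2[[lc]]), as.data.frame(tfs[[lc]]),
                 tolerance = 1e-12)
})

test_that("ray compositing follows the front-to-back closed forms", {
  bg <- c(0.1, 0.2, 0.3)
  expect_equal(composite_ray(matrix(0, 0, 3), numeric(0), bg), bg)
  expect_equal(composite_ray(rbind(c(0.3, 0.6, 0.9)), 1, bg),
               c(0.3, 0.6, 0.9))
  # (red, 0.5) then (blue, 1.0) -> equal parts red and blue
  out <- composite_ray(rbind(c(1, 0, 0), c(0, 0, 1)), c(0.5, 1))
  expect_equal(out, c(0.5, 0, 0.5))
  # homogeneous slab: total opacity 1 - (1-a)^n
  n <- 40; a <- 0.05
  col <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  want_A <- 1 - (1 - a)^n
  expect_equal(composite_ray(col, rep(a, n), c(0, 0, 0)),
               c(want_A, 0, 0), tolerance = 1e-6)
})

test_that("cameras validate their geometry", {
  expect_error(camera(view = c(0, 0, 0)), "degenerate")
  expect_error(camera(view = c(0, 0, 1), up = c(0, 0, 1)), "parallel")
  expect_error(camera(step_mm = 0), "positive")
  cam <- camera(view = c(0, 1, 0), up = c(0, 0, 1))
  expect_equal(sum(cam$view * cam$up), 0, tolerance = 1e-12)
  expect_equal(sum(cam$right^2), 1, tolerance = 1e-12)
})

slab_scene <- function(alpha_scale = 1) {
  d <- c(24, 24, 24)
  vol <- volume(array(100, d), spacing = c(0.4, 0.4, 0.4))
  lab <- array(0L, d)
  lab[5:20, 8:15, 5:20] <- 1L  # slab facing a +y viewer
  list(vol = vol, labels = labelmap(lab, vol),
       tfs = list("0" = transfer_function(c(0, 1000), 0, 0, 0, 0),
                  "1" = transfer_function(c(0, 1000), 1, 0, 0,
                                          0.3 * alpha_scale),
                  "2" = transfer_function(c(0, 1000), 0.8, 0.8, 0.8, 0.2),
                  "3" = transfer_function(c(0, 1000), 1, 0.9, 0, 0.9)))
}

test_that("an all-transparent scene renders pure background", {
  d <- c(16, 16, 16)
  vol <- volume(array(50, d), spacing = c(0.4, 0.4, 0.4))
  lab <- labelmap(array(0L, d), vol)
  cam <- camera(size_px = 24, window_mm = 8, background = c(0.2, 0.1, 0))
  img <- render(vol, lab, default_transfer_functions(100), cam)
  expect_equal(range(img[, , 1]), c(0.2, 0.2))
  expect_equal(range(img[, , 2]), c(0.1, 0.1))
  expect_equal(range(img[, , 3]), c(0, 0))
})

test_that("a vessel-labelled slab composites to its closed form", {
  sc <- slab_scene()
  cam <- camera(view = c(0, 1, 0), size_px = 32, window_mm = 9.6,
                step_mm = 0.4)
  img <- render(sc$vol, sc$labels, sc$tfs, cam)
  # central pixels: the ray crosses the 8-voxel slab depth; interior
  # samples are fully red, boundary samples partially (membership)
  centre <- img[16, 16, ]
  lo <- 1 - (1 - 0.3)^7   # at least 7 full-opacity steps
  expect_gt(centre[1], lo)
  expect_equal(centre[2], 0)
  expect_equal(centre[3], 0)
  # corners see nothing
  expect_equal(img[1, 1, ], c(0, 0, 0))
})

test_that("rendering is deterministic", {
  st <- clean_stages()
  ph <- clean_ph()
  cam <- camera_angles(15, 10, size_px = 48, window_mm = 30)
  tfs <- default_transfer_functions(ph$ciss)
  i1 <- render(ph$ciss, st$labels_pre, tfs, cam)
  i2 <- render(ph$ciss, st$labels_pre, tfs, cam)
  expect_identical(as.vector(i1), as.vector(i2))
})

test_that("opacity correction makes renders step-size invariant", {
  # smooth scene: blurred slab labels with a smooth volume
  d <- c(24, 24, 24)
  idx <- as.matrix(expand.grid(0:23, 0:23, 0:23))
  vol <- volume(array(300 + 200 * exp(-rowSums((idx - 11.5)^2) / 80), d),
                spacing = c(0.4, 0.4, 0.4))
  lab <- array(0L, d)
  lab[rowSums((idx - 11.5)^2) < 49] <- 1L
  dim(lab) <- d
  labels <- labelmap(lab, vol)
  tfs <- default_transfer_functions(1100)
  cam1 <- camera(size_px = 32, window_mm = 9.6, step_mm = 0.4)
  cam2 <- camera(size_px = 32, window_mm = 9.6, step_mm = 0.2)
  img1 <- render(vol, labels, tfs, cam1)
  img2 <- render(vol, labels, tfs, cam2)
  expect_lt(mean(abs(img1 - img2)), 0.02)
})

test_that("centerline visibility measures projected redness", {
  sc <- slab_scene()
  cam <- camera(view = c(0, 1, 0), size_px = 64, window_mm = 9.6,
                step_mm = 0.4)
  img <- render(sc$vol, sc$labels, sc$tfs, cam)
  # a line through the slab centre is visible, one far outside is not
  inside <- cbind(seq(2.4, 7.6, by = 0.4), 4.6, 4.8)
  outside <- cbind(seq(2.4, 7.6, by = 0.4), 4.6, 40)
  expect_gt(centerline_visibility(img, inside, red_margin = 0.6), 0.9)
  expect_equal(centerline_visibility(img, outside), 0)
})
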