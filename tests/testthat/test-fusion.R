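test_that("the inversion line is anchored at the two maxima", {
  mk <- function(vals) volume(array(vals, c(2, 2, 2)))
  ciss <- mk(c(0, 200, 500, 1000, 30, 40, 50, 60))
  tof <- mk(c(0, 100, 200, 500, 10, 20, 30, 40))
  ln <- fit_inversion_line(ciss, tof)
  expect_equal(ln$slope, -2)
  expect_equal(predict(ln, 0), 1000)
  expect_equal(predict(ln, 500), 0)
  # equal maxima: line(v) = M - v
  ln2 <- fit_inversion_line(mk(c(rep(0, 7), 800)), mk(c(rep(0, 7), 800)))
  expect_equal(predict(ln2, 300), 500)
})

test_that("line anchors equal exhaustively scanned maxima", {
  set.seed(31)
  for (i in 1:5) {
    a <- array(runif(5^3, 0, 1000), c(5, 5, 5))
    b <- array(runif(5^3, 0, 700), c(5, 5, 5))
    ln <- fit_inversion_line(volume(a), volume(b))
    # brute-force scan oracle
    ma <- -Inf; for (x in a) ma <- max(ma, x)
    mb <- -Inf; for (x in b) mb <- max(mb, x)
    expect_equal(ln$max_ciss, ma)
    expect_equal(ln$max_tof, mb)
  }
})

test_that("degenerate fusion inputs error", {
  v <- volume(array(runif(8), c(2, 2, 2)))
  expect_error(fit_inversion_line(volume(array(1, c(2, 2, 2))), v),
               "degenerate|constant")
  neg <- volume(array(c(-1, runif(7)), c(2, 2, 2)))
  expect_error(fit_inversion_line(neg, v), "non-negative")
})

test_that("fusion replaces only masked voxels, on the line, clamped", {
  set.seed(33)
  d <- c(6, 6, 6)
  ciss <- volume(array(runif(prod(d), 0, 1000), d))
  tof <- volume(array(runif(prod(d), 0, 600), d))
  ln <- fit_inversion_line(ciss, tof)
  mask <- array(runif(prod(d)) < 0.4, d)

  fused <- apply_fusion(ciss, tof, mask, ln)
  # unmasked voxels bit-identical
  expect_identical(fused$data[!mask], ciss$data[!mask])
  # masked voxels follow the line
  expect_equal(fused$data[mask],
               pmax(0, predict(ln, tof$data[mask])), tolerance = 1e-12)
  # range containment
  expect_true(all(fused$data >= 0 & fused$data <= ln$max_ciss))
  # endpoints: tof maximum maps to 0
  imax <- which(tof$data == ln$max_tof)
  mask2 <- array(FALSE, d); mask2[imax] <- TRUE
  expect_equal(apply_fusion(ciss, tof, mask2, ln)$data[imax], 0)
  # empty mask is the identity
  expect_identical(apply_fusion(ciss, tof, array(FALSE, d), ln)$data,
                   ciss$data)
  # half the TOF maximum maps to half the CISS maximum
  tof2 <- volume(array(ln$max_tof / 2, d))
  expect_equal(unique(as.vector(
    apply_fusion(ciss, tof2, array(TRUE, d), ln)$data)),
    ln$max_ciss / 2)
})

test_that("fusion strictly reverses the TOF intensity order", {
  set.seed(34)
  d <- c(5, 5, 5)
  ciss <- volume(array(runif(prod(d), 0, 900), d))
  tof <- volume(array(sample(seq(0, 500, by = 4), prod(d)), d))
  ln <- fit_inversion_line(ciss, tof)
  fused <- apply_fusion(ciss, tof, array(TRUE, d), ln)
  ord <- order(tof$data)
  expect_true(all(diff(fused$data[ord]) < 0 | diff(tof$data[ord]) == 0))
})

test_that("robust anchoring ignores isolated hot voxels and clamps", {
  set.seed(35)
  a <- array(runif(12^3, 0, 100), c(12, 12, 12)); a[1, 1, 1] <- 1e5
  ciss <- volume(a)
  tof <- volume(array(runif(12^3, 0, 100), c(12, 12, 12)))
  ln <- fit_inversion_line(ciss, tof, robust = TRUE)
  expect_lt(ln$max_ciss, 1000)
  fused <- apply_fusion(ciss, tof, array(TRUE, c(12, 12, 12)), ln)
  expect_true(all(fused$data >= 0))
})

test_that("the composed fusion pipeline repairs flow voids", {
  ph <- flow_void_ph()
  st <- cached("fv_stages", function() run_fusion_stages(flow_void_ph()))
  csfm <- mean(ph$ciss$data[ph$csf_only_mask])
  lv <- Reduce(`|`, lapply(ph$vessels[c("basilar", "vertebral_l",
                                        "vertebral_r")], `[[`, "mask"))
  # before fusion the lumen has lost its CSF contrast almost everywhere
  expect_lt(mean(ph$ciss$data[lv] < 0.5 * csfm), 0.6)
  # after fusion nearly every large-vessel voxel is vessel-dark again
  expect_gte(mean(st$fus$fused$data[lv] < 0.5 * csfm), 0.95)
  # the basilar lumen is uniformly hypointense: nothing above the CSF mean
  bas <- ph$vessels$basilar$mask
  expect_true(all(st$fus$fused$data[bas] < csfm))
})

test_that("fusing with an empty vessel mask returns the CISS volume", {
  ph <- clean_ph()
  seeds <- phantom_seeds(ph)
  out <- fuse_pipeline(ph$ciss, ph$tof, rigid_transform(),
                       tof_params = list(seeds = seeds$tof, lower = 1e9))
  expect_identical(out$fused$data, ph$ciss$data)
  expect_true(all(out$fused$data <= out$line$max_ciss))
})
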