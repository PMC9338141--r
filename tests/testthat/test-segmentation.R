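test_that("region growing matches the flood-fill oracle", {
  set.seed(101)
  for (i in 1:30) {
    cs <- random_grow_case()
    got <- region_grow(cs$vol, cs$seeds, cs$lower, cs$upper, cs$bbox,
                       cs$connectivity)
    want <- flood_fill_oracle(cs$vol, cs$seeds, cs$lower, cs$upper,
                              cs$bbox, cs$connectivity)
    expect_identical(got, want)
  }
})

test_that("region growing trivial cases behave as specified", {
  d <- c(8, 8, 8)
  v <- volume(array(0.5, d))
  # out-of-range seeds contribute nothing
  expect_false(any(region_grow(v, c(1, 1, 1), 0.8, 0.9)))
  # uniform in-range volume fills the whole bbox and nothing else
  bb <- bounding_box(c(1, 1, 1), c(5, 5, 5))
  m <- region_grow(v, c(2, 2, 2), 0, 1, bb)
  expect_equal(sum(m), 4^3)
  expect_true(all(which(m, arr.ind = TRUE) >= 2))
  # full grid when bbox covers it
  expect_true(all(region_grow(v, c(0, 0, 0), 0, 1)))
  # thresholds are inclusive at both ends
  v2 <- volume(array(c(1, 2, 2, 2, 2, 2, 2, 3), c(2, 2, 2)))
  expect_equal(sum(region_grow(v2, c(1, 0, 0), 1, 2)), 7)
  expect_error(region_grow(v, c(0, 0, 0), 2, 1), "lower")
  expect_error(region_grow(v, c(9, 0, 0), 0, 1), "bounds")
})

test_that("disconnected components grow separately", {
  a <- array(0, c(12, 6, 6))
  a[2:4, 2:4, 2:4] <- 1     # component A
  a[8:10, 2:4, 2:4] <- 1    # component B
  v <- volume(a)
  m <- region_grow(v, c(2, 2, 2), 0.5, 1.5)
  expect_equal(sum(m), 27)
  expect_false(any(m[8:10, , ]))
})

test_that("growing is monotone in thresholds and bbox", {
  set.seed(55)
  for (i in 1:10) {
    cs <- random_grow_case()
    m1 <- region_grow(cs$vol, cs$seeds, cs$lower, cs$upper, cs$bbox,
                      cs$connectivity)
    wide <- region_grow(cs$vol, cs$seeds, cs$lower - 0.1,
                        cs$upper + 0.1, NULL, cs$connectivity)
    expect_true(all(wide[m1]))
  }
})

test_that("TOF vessel growing uses a lower threshold only and tags label 1", {
  a <- array(50, c(16, 8, 8)); a[4:12, 3:5, 3:5] <- 800
  v <- volume(a)
  m <- segment_tof_vessels(v, c(5, 3, 3), lower = 300)
  expect_identical(attr(m, "label"), 1L)
  expect_equal(sum(m), 9 * 3 * 3)
  expect_false(any(segment_tof_vessels(v, c(5, 3, 3), lower = 1e5)))
})

test_that("label assembly applies the nerves > brainstem > CSF priority", {
  ref <- volume(array(0, c(6, 6, 6)))
  expect_true(all(assemble_labelmap(ref)$data == 0))
  set.seed(77)
  csf <- array(runif(216) < 0.5, c(6, 6, 6))
  bs <- array(runif(216) < 0.3, c(6, 6, 6))
  nv <- array(runif(216) < 0.2, c(6, 6, 6))
  lm <- assemble_labelmap(ref, csf, bs, nv)
  # per-voxel oracle
  want <- ifelse(nv, 3, ifelse(bs, 2, ifelse(csf, 1, 0)))
  expect_equal(lm$data, array(as.double(want), dim(want)))
  # partition: label counts sum to the voxel count
  expect_equal(sum(tabulate(as.vector(lm$data) + 1L, 4)), 216)
  expect_error(assemble_labelmap(ref, array(TRUE, c(5, 6, 6))), "shape")
})

test_that("TOF vessels merge into label 1 without erasing nerves", {
  ref <- volume(array(0, c(4, 4, 4)))
  lab <- labelmap(array(rep(0:3, each = 16), c(4, 4, 4)), ref)
  expect_equal(merge_vessel_labels(lab, array(FALSE, c(4, 4, 4)))$data,
               lab$data)
  m <- array(TRUE, c(4, 4, 4))
  merged <- merge_vessel_labels(lab, m)
  expect_true(all(merged$data[lab$data != 3] == 1))  # incl. brainstem
  expect_true(all(merged$data[lab$data == 3] == 3))
})

test_that("contour-fused vessel voxels are reclaimed from the brainstem", {
  st <- hard_stages()
  ph <- hard_ph()
  pica <- ph$vessels$pica_l
  near_bs <- pica$mask & neurofuse:::dilate6(ph$brainstem_mask) &
    !ph$nerve_mask  # nerve voxels are never vessel-relabelled
  # pre-fusion the delineated brainstem absorbed the contour-fused voxels
  expect_gt(mean(st$labels_pre$data[near_bs] == 2), 0.5)
  # after merging the TOF mask they carry the vessel label again
  expect_true(all(st$fus$labels$data[near_bs] == 1))
})

test_that("delineation absorbs only brainstem-like neighbours", {
  ph <- clean_ph()
  bs <- delineate_brainstem(ph$ciss, ph$brainstem_mask)
  expect_true(all(bs[ph$brainstem_mask]))
  added <- bs & !ph$brainstem_mask
  # on a clean phantom nothing vessel-like is absorbed
  vessels <- Reduce(`|`, lapply(ph$vessels, `[[`, "mask"))
  expect_equal(sum(added & vessels), 0)
})

test_that("label optimization removes specks but keeps vessels", {
  st <- hard_stages()
  ph <- hard_ph()
  opt <- st$labels_post
  vessels <- Reduce(`|`, lapply(ph$vessels, `[[`, "mask"))
  kept <- st$fus$labels$data == 1 & vessels
  # TOF-confirmed vessel voxels are always preserved
  confirmed <- kept & st$fus$vessel_mask
  expect_true(all(opt$data[confirmed] == 1))
  # and nearly all vessel voxels survive overall (isolated fragments of
  # artifact-corrupted small vessels may be clipped)
  expect_gt(mean(opt$data[kept] == 1), 0.98)
  # spurious dark specks inside the pulsation sphere get demoted
  csfm <- mean(ph$ciss$data[ph$csf_only_mask])
  speck <- st$fus$labels$data == 1 & !vessels &
    st$fus$fused$data < 0.5 * csfm & !ph$nerve_mask
  expect_gt(sum(speck), 0)
  expect_lt(sum(opt$data[speck] == 1), sum(speck))
})

test_that("dice coefficient behaves at the boundaries", {
  a <- array(FALSE, c(3, 3, 3))
  expect_equal(dice(a, a), 1)
  b <- a; b[1, 1, 1] <- TRUE
  expect_equal(dice(b, b), 1)
  expect_equal(dice(a, b), 0)
})
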