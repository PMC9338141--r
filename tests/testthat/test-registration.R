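test_that("joint histogram matches brute-force counting", {
  # identical constant-gradient images, identity transform, 2 bins:
  # every voxel pairs a value with itself -> all mass on the diagonal
  d <- c(6, 6, 6)
  g <- array(seq(0, 1, length.out = prod(d)), d)
  v <- volume(g, spacing = c(1, 1, 1))
  h <- joint_histogram(v, v, bins = 2L)
  expect_equal(sum(h$counts), prod(d))
  expect_equal(h$counts[1, 2] + h$counts[2, 1], 0)
  # brute-force per-voxel binning oracle
  bin <- ifelse(g < 0.5, 1, 2)
  want <- table(factor(bin, 1:2))
  expect_equal(diag(h$counts), as.vector(want), ignore_attr = TRUE)

  # two constant images: one nonzero cell holding all samples
  c1 <- volume(array(3, d)); c2 <- volume(array(7, d))
  h2 <- joint_histogram(c1, c2, bins = 4L)
  expect_equal(sum(h2$counts > 0), 1)
  expect_equal(sum(h2$counts), prod(d))

  # checkerboard vs its inversion: all mass on the anti-diagonal
  idx <- as.matrix(expand.grid(0:5, 0:5, 0:5))
  chk <- array((rowSums(idx) %% 2), d)
  v1 <- volume(chk); v2 <- volume(1 - chk)
  h3 <- joint_histogram(v1, v2, bins = 2L)
  expect_equal(h3$counts[1, 1] + h3$counts[2, 2], 0)
  expect_equal(h3$counts[1, 2] + h3$counts[2, 1], prod(d))
})

test_that("joint histogram with no overlap errors", {
  v <- volume(array(runif(4^3), c(4, 4, 4)))
  far <- rigid_transform(diag(3), c(1000, 0, 0))
  expect_error(joint_histogram(v, v, far), "no overlap")
})

test_that("NMI takes its closed-form values", {
  d <- c(8, 8, 8)
  set.seed(2)
  v <- volume(array(runif(prod(d)), d))
  expect_equal(nmi(joint_histogram(v, v, bins = 16L)), 2, tolerance = 1e-12)

  # hand-computed 2x2 histogram: equal masses on the diagonal pair is
  # perfectly informative; adding off-diagonal mass lowers it
  expect_equal(nmi(matrix(c(5, 0, 0, 5), 2)), 2, tolerance = 1e-12)
  cnt <- matrix(c(2, 1, 1, 2), 2)
  hj <- -sum(rep(c(2, 1) / 6, 2) * log(rep(c(2, 1) / 6, 2)))
  expect_equal(nmi(cnt), 2 * log(2) / hj, tolerance = 1e-12)

  # independent noise: NMI approaches its lower bound 1
  set.seed(3)
  a <- volume(array(runif(prod(d)), d))
  b <- volume(array(runif(prod(d)), d))
  val <- nmi(joint_histogram(a, b, bins = 4L))
  expect_gt(val, 1)
  expect_lt(val, 1.1)

  expect_error(nmi(joint_histogram(volume(array(1, d)), v, bins = 4L)),
               "degenerate")
})

test_that("NMI is invariant to bin relabeling and image swap", {
  set.seed(9)
  counts <- matrix(rpois(64, 3), 8, 8)
  perm <- sample(8)
  expect_equal(nmi(counts), nmi(counts[perm, perm]))
  expect_equal(nmi(counts), nmi(t(counts)))
})

test_that("reformat honours its resampling contract", {
  set.seed(6)
  v <- volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)), spacing = c(1, 1, 1))
  out <- reformat(v, rigid_transform(), v)
  expect_equal(out$data, v$data, tolerance = 1e-12)

  # pure translation by whole voxels: shifted copy, zero at exposed face
  shift <- rigid_transform(diag(3), c(2, 0, 0))  # fixed x -> moving x+2
  out2 <- reformat(v, shift, v)
  expect_equal(out2$data[1:4, , ], v$data[3:6, , ], tolerance = 1e-12)
  expect_true(all(out2$data[5:6, , ] == 0))

  # output geometry equals the reference's exactly
  ref <- volume(array(0, c(5, 5, 5)), spacing = c(0.4, 0.4, 0.4),
                origin = c(1, 1, 1))
  out3 <- reformat(v, random_rigid(center = c(2, 2, 2)), ref)
  expect_identical(dim(out3), dim(ref))
  expect_identical(out3$spacing, ref$spacing)
  expect_identical(out3$origin, ref$origin)
  expect_identical(out3$direction, ref$direction)
})

test_that("reformatting there and back blurs but preserves content", {
  # smooth blob volume; T then T^-1 must return close to the original
  d <- c(32, 32, 32)
  idx <- as.matrix(expand.grid(0:31, 0:31, 0:31))
  blob <- array(exp(-rowSums((idx - 15.5)^2) / 60), d)
  v <- volume(blob, spacing = c(1, 1, 1))
  set.seed(12)
  tr <- random_rigid(max_angle_deg = 6, max_trans_mm = 3,
                     center = c(15.5, 15.5, 15.5))
  there <- reformat(v, tr, v)
  back <- reformat(there, invert_transform(tr), v)
  interior <- array(FALSE, d); interior[5:28, 5:28, 5:28] <- TRUE
  mae <- mean(abs(back$data[interior] - v$data[interior]))
  expect_lt(mae, 0.05 * diff(range(v$data)))
})

test_that("self-registration recovers the identity", {
  ph <- clean_ph()
  tr <- register_rigid(ph$ciss, ph$ciss,
                       options = list(cycles = 1L, polish = FALSE))
  expect_lt(rotation_angle(tr), 0.1)
  expect_lt(sqrt(sum(tr$translation^2)) +
              sum(abs(transform_points(tr, c(19, 19, 19)) - c(19, 19, 19))),
            0.2)
  expect_gte(attr(tr, "nmi"), attr(tr, "nmi_init"))
})

test_that("a known misalignment is recovered to sub-voxel accuracy", {
  ctr <- c(19, 19, 19)
  T_true <- euler_transform(c(0, 0, 4), c(2, -3, 1), center = ctr)
  ph <- generate_phantom(phantom_spec(seed = 21, misalign = T_true,
                                      noise_scale = 0))
  T_rec <- register_rigid(ph$ciss, ph$tof)
  err <- transform_error(T_rec, T_true, at = ctr)
  expect_lt(err["rotation_deg"], 0.2)
  expect_lt(err["translation_mm"], 0.2)
})

test_that("block-mean downsampling preserves world geometry", {
  v <- volume(array(runif(16^3), c(16, 16, 16)), spacing = c(0.4, 0.4, 0.4))
  v2 <- downsample_volume(v, 2)
  expect_equal(dim(v2), c(8, 8, 8))
  expect_equal(v2$spacing, rep(0.8, 3))
  # centre of the first block
  expect_equal(v2$origin, rep(0.2, 3))
  expect_equal(v2$data[1, 1, 1], mean(v$data[1:2, 1:2, 1:2]))
})
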