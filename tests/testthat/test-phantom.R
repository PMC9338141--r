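test_that("phantom generation is seed-deterministic", {
  s1 <- generate_phantom(phantom_spec(seed = 42, shape = 96))
  s2 <- generate_phantom(phantom_spec(seed = 42, shape = 96))
  expect_identical(s1$ciss$data, s2$ciss$data)
  expect_identical(s1$tof$data, s2$tof$data)
  expect_identical(s1$truth_labels$data, s2$truth_labels$data)
  s3 <- generate_phantom(phantom_spec(seed = 43, shape = 96))
  expect_false(identical(s1$ciss$data, s3$ciss$data))
})

test_that("tube masks match analytic capsule volumes", {
  # a tube around a polyline is a capsule: cylinder plus spherical caps
  ph <- clean_ph()
  for (nm in names(ph$vessels)) {
    v <- ph$vessels[[nm]]
    L <- sum(sqrt(rowSums(diff(v$centerline)^2)))
    analytic <- (pi * v$radius^2 * L + 4 / 3 * pi * v$radius^3) / 0.4^3
    expect_lt(abs(sum(v$mask) - analytic) / analytic, 0.1)
  }
})

test_that("the phantom reproduces the two sequences' contrasts", {
  ph <- clean_ph()
  sp <- ph$spec
  csf <- ph$ciss$data[ph$csf_only_mask]
  bs <- ph$ciss$data[ph$brainstem_mask]
  # CISS: CSF bright, brainstem/vessels dark, by many noise SDs
  expect_gt(mean(csf) - mean(bs), 3 * sp$ciss_sd[["csf"]])
  vessels <- Reduce(`|`, lapply(ph$vessels, `[[`, "mask"))
  expect_gt(mean(csf) - mean(ph$ciss$data[vessels]),
            3 * sp$ciss_sd[["csf"]])
  # TOF: vessels bright over everything else
  expect_gt(mean(ph$tof$data[vessels]) - mean(ph$tof$data[!vessels]),
            5 * sp$tof_sd[["vessel"]])
})

test_that("ground-truth labels partition the grid and use the 4 codes", {
  ph <- clean_ph()
  lab <- ph$truth_labels$data
  expect_true(all(lab %in% 0:3))
  counts <- tabulate(as.vector(lab) + 1L, 4)
  expect_equal(sum(counts), prod(dim(lab)))
  # vessels carry the CSF/vessel code 1
  vessels <- Reduce(`|`, lapply(ph$vessels, `[[`, "mask"))
  expect_gt(mean(lab[vessels & !ph$nerve_mask] == 1), 0.99)
})

test_that("intensity injectors never touch the ground-truth labels", {
  clean <- generate_phantom(phantom_spec(seed = 19))
  hard <- generate_phantom(hard_phantom_spec(seed = 19))
  expect_identical(clean$truth_labels$data, hard$truth_labels$data)
})

test_that("structures must fit inside the grid", {
  expect_error(generate_phantom(phantom_spec(shape = 48)),
               "outside the grid")
})

test_that("flow voids raise the lumen core to CSF and spare the shell", {
  ph <- clean_ph()
  sp <- ph$spec
  out <- inject_flow_void(ph$ciss, ph$vessels, "basilar", fraction = 0.5,
                          csf_mean = 1000, csf_sd = 30, seed = 5)
  bas <- ph$vessels$basilar
  dist <- neurofuse:::tube_distance_field(ph$ciss, bas$centerline)
  core <- dist <= 0.5 * bas$radius
  shell <- bas$mask & dist > 0.55 * bas$radius
  # central lumen is CSF-like within one noise SD
  expect_lt(abs(mean(out$data[core]) - 1000), sp$ciss_sd[["csf"]])
  # outer shell untouched, as is everything outside the vessel
  expect_identical(out$data[shell], ph$ciss$data[shell])
  expect_identical(out$data[!bas$mask], ph$ciss$data[!bas$mask])
  # no vessels selected: identity
  expect_identical(inject_flow_void(ph$ciss, ph$vessels,
                                    character(0))$data, ph$ciss$data)
  expect_error(inject_flow_void(ph$ciss, ph$vessels, "arteria"),
               "unknown vessel")
  expect_error(inject_flow_void(ph$ciss, ph$vessels, "sca_l"),
               "large vessels")
})

test_that("the pulsation cloud is a local, seeded perturbation", {
  ph <- clean_ph()
  ctr <- c(19.2, 13.2, 19)
  expect_identical(inject_pulsation_cloud(ph$ciss, ctr, 6, 0)$data,
                   ph$ciss$data)
  out <- inject_pulsation_cloud(ph$ciss, ctr, 6, 180, seed = 8)
  w <- grid_points(ph$ciss)
  r2 <- array(rowSums(sweep(w, 2, ctr, "-")^2), dim(ph$ciss))
  inside <- r2 <= 36 & ph$csf_only_mask
  outside <- r2 > 36
  # locality: nothing beyond the sphere changes
  expect_identical(out$data[outside], ph$ciss$data[outside])
  # the perturbation inflates the local intensity variance
  expect_gt(stats::var(out$data[inside]), 1.5 * stats::var(ph$ciss$data[inside]))
  # determinism
  out2 <- inject_pulsation_cloud(ph$ciss, ctr, 6, 180, seed = 8)
  expect_identical(out$data, out2$data)
  expect_error(inject_pulsation_cloud(ph$ciss, c(999, 0, 0), 6, 100),
               "outside")
})

test_that("contour fusion pulls touching vessel voxels to brainstem", {
  ph <- clean_ph()
  sp <- ph$spec
  out <- inject_contour_fusion(ph$ciss, ph$vessels, ph$brainstem_mask,
                               "pica_l", seed = 9)
  touch <- ph$vessels$pica_l$mask & neurofuse:::dilate6(ph$brainstem_mask)
  expect_gt(sum(touch), 0)
  expect_lt(abs(mean(out$data[touch]) - sp$ciss_mean[["brainstem"]]),
            sp$ciss_sd[["brainstem"]])
  # vessels away from the brainstem are untouched
  far <- ph$vessels$pica_l$mask & !touch
  expect_identical(out$data[far], ph$ciss$data[far])
  expect_identical(inject_contour_fusion(ph$ciss, ph$vessels,
                                         ph$brainstem_mask,
                                         character(0))$data, ph$ciss$data)
  # the right PICA runs clear of the brainstem by design
  expect_error(inject_contour_fusion(ph$ciss, ph$vessels,
                                     ph$brainstem_mask, "pica_r"),
               "does not touch")
})

test_that("TOF dropout scales vessel signal toward background", {
  ph <- clean_ph()
  expect_identical(tof_dropout(ph$tof, ph$vessels, "aica_l", 1)$data,
                   ph$tof$data)
  bg <- ph$spec$tof_mean[["rest"]]
  m <- ph$vessels$aica_l$mask
  out0 <- tof_dropout(ph$tof, ph$vessels, "aica_l", 0, background = bg)
  expect_lt(abs(mean(out0$data[m]) - bg), 3)
  # intermediate attenuation scales the mean linearly
  outh <- tof_dropout(ph$tof, ph$vessels, "aica_l", 0.5, background = bg)
  expect_equal(mean(outh$data[m]) - bg,
               0.5 * (mean(ph$tof$data[m]) - bg), tolerance = 1e-9)
  expect_identical(out0$data[!m], ph$tof$data[!m])
})

test_that("the misalignment transform moves the TOF scene as declared", {
  ctr <- c(19, 19, 19)
  T_true <- euler_transform(c(0, 0, 3), c(1.2, -0.8, 0.6), center = ctr)
  ph <- generate_phantom(phantom_spec(seed = 13, misalign = T_true,
                                      noise_scale = 0))
  aligned <- generate_phantom(phantom_spec(seed = 13, noise_scale = 0))
  # reformatting through the true transform restores alignment
  back <- reformat(ph$tof, T_true, ph$ciss)
  vessels <- Reduce(`|`, lapply(aligned$vessels, `[[`, "mask"))
  expect_gt(mean(back$data[vessels]), 0.85 * ph$spec$tof_mean[["vessel"]])
  # whereas the raw TOF is visibly displaced
  expect_lt(mean(ph$tof$data[vessels]), 0.8 * ph$spec$tof_mean[["vessel"]])
})

test_that("vessel truth serializes and reconstructs through JSON", {
  ph <- clean_ph()
  f <- tempfile(fileext = ".json")
  write_vessel_truth(ph$vessels, f)
  vt <- read_vessel_truth(f, ph$ciss)
  expect_setequal(names(vt), names(ph$vessels))
  for (nm in c("basilar", "pica_l")) {
    expect_equal(vt[[nm]]$centerline, ph$vessels[[nm]]$centerline,
                 tolerance = 1e-9, ignore_attr = TRUE)
    # masks are rebuilt from the serialized centerline; curvature makes
    # a handful of boundary voxels differ from the generator's mask
    expect_gt(dice(vt[[nm]]$mask, ph$vessels[[nm]]$mask), 0.99)
    expect_equal(vt[[nm]]$relevant, ph$vessels[[nm]]$relevant)
  }
})

test_that("the artifact census mirrors the generator switches", {
  cen <- artifact_census(hard_ph())
  expect_true(cen$flow_void[cen$vessel == "basilar"])
  expect_true(cen$contour_fusion[cen$vessel == "pica_l"])
  expect_false(cen$contour_fusion[cen$vessel == "pica_r"])
  expect_true(all(cen$tof_dropout[cen$vessel %in%
                                    c("aica_l", "aica_r", "sca_l", "sca_r")]))
  cen0 <- artifact_census(clean_ph())
  expect_false(any(cen0$flow_void | cen0$contour_fusion | cen0$tof_dropout))
})
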