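#' Specification of the synthetic posterior-fossa phantom
#'
#' Builds the parameter set for [generate_phantom()]: grid, anatomy
#' (brainstem ellipsoid, CSF cistern shell, named vessel and nerve tubes),
#' per-tissue intensity distributions for both MR contrasts, artifact
#' switches, the TOF misalignment transform, and the RNG seed. The
#' defaults model a 96^3 grid of 0.4 mm isotropic voxels (a 38.4 mm cube
#' centred on the prepontine and cerebellopontine cisterns) with the
#' vessel set {basilar, vertebral_l/r, pica_l/r, aica_l/r, sca_l/r} and
#' the nerve set {CN V, CN VII/VIII, CN IX} on both sides.
#'
#' Intensity defaults (arbitrary units): CISS — CSF 1000, vessels 160,
#' nerves 200, brainstem 320, remaining structures 30; TOF — vessels 900,
#' brainstem 120, nerves 110, CSF 60, background 25. CISS thus shows
#' hyperintense CSF against hypointense nerves/vessels/brainstem, TOF
#' shows bright flowing blood on a dark background.
#'
#' @param shape grid size per axis (voxels).
#' @param voxel_mm isotropic voxel size, mm.
#' @param artifacts character vector of artifact switches to enable, any
#'   of `"flow_void"`, `"pulsation_cloud"`, `"contour_fusion"`,
#'   `"tof_dropout"`.
#' @param misalign [rigid_transform()] applied to the TOF volume (CISS
#'   world to TOF world); identity by default.
#' @param noise_scale multiplier on all per-tissue noise SDs.
#' @param seed integer RNG seed; the phantom is bit-reproducible given it.
#' @param ... named overrides of any default component (see the returned
#'   list's names).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), voxel_mm = 0.4,
                         artifacts = character(), misalign = NULL,
                         noise_scale = 1, seed = 1L, ...) {
  c0 <- c(19.2, 22, 19.2)
  semi <- c(8, 7, 13)
  surf <- function(dir, clearance)
    ellipsoid_surface_point(c0, semi, dir, clearance)
  mirror <- function(pts) {
    pts[, 1] <- 2 * c0[1] - pts[, 1]
    pts
  }
  pica_l_pts <- rbind(c(22.2, 15.0, 4.8),
                      surf(c(0.60, -0.65, -0.45), 0.75),
                      surf(c(0.75, -0.30, -0.55), 0.75),
                      c(27.0, 20.0, 13.0))
  pica_r_pts <- rbind(c(16.2, 15.0, 4.8),
                      surf(c(-0.60, -0.65, -0.45), 1.6),
                      surf(c(-0.75, -0.30, -0.55), 1.6),
                      c(11.4, 20.0, 13.0))
  aica_l_pts <- rbind(c(19.2, 13.4, 19.5), c(23.25, 15.1, 19.0),
                      c(27.4, 19.4, 17.7))
  sca_l_pts <- rbind(c(19.2, 13.25, 28.3), c(23.0, 15.0, 27.6),
                     c(26.0, 18.5, 26.8))
  vessels <- list(
    basilar = list(points = rbind(c(19.2, 13.7, 8), c(19.2, 13.2, 19),
                                  c(19.2, 13.0, 30)),
                   radius = 1.6, relevant = c(0.35, 0.75), small = FALSE),
    vertebral_l = list(points = rbind(c(22.6, 15.2, 4), c(19.6, 13.9, 8.2)),
                       radius = 1.3, relevant = c(0.5, 1), small = FALSE),
    vertebral_r = list(points = rbind(c(15.8, 15.2, 4), c(18.8, 13.9, 8.2)),
                       radius = 1.3, relevant = c(0.5, 1), small = FALSE),
    pica_l = list(points = pica_l_pts, radius = 0.7,
                  relevant = c(0.45, 0.85), small = TRUE),
    pica_r = list(points = pica_r_pts, radius = 0.7,
                  relevant = c(0.45, 0.85), small = TRUE),
    aica_l = list(points = aica_l_pts, radius = 0.6,
                  relevant = c(0.5, 0.9), small = TRUE),
    aica_r = list(points = mirror(aica_l_pts), radius = 0.6,
                  relevant = c(0.5, 0.9), small = TRUE),
    sca_l = list(points = sca_l_pts, radius = 0.6,
                 relevant = c(0.5, 0.9), small = TRUE),
    sca_r = list(points = mirror(sca_l_pts), radius = 0.6,
                 relevant = c(0.5, 0.9), small = TRUE)
  )
  nerve_tube <- function(dir, root_clear, tip_clear)
    rbind(surf(dir, root_clear), surf(dir, tip_clear))
  nerves <- list(
    cn5_l = list(points = nerve_tube(c(0.75, -0.50, 0.35), -0.3, 5.5),
                 radius = 0.9),
    cn5_r = list(points = nerve_tube(c(-0.75, -0.50, 0.35), -0.3, 5.5),
                 radius = 0.9),
    cn78_l = list(points = nerve_tube(c(0.85, -0.40, 0.0), -0.3, 5.0),
                  radius = 0.8),
    cn78_r = list(points = nerve_tube(c(-0.85, -0.40, 0.0), -0.3, 5.0),
                  radius = 0.8),
    cn9_l = list(points = nerve_tube(c(0.70, -0.55, -0.65), -0.3, 4.5),
                 radius = 0.7),
    cn9_r = list(points = nerve_tube(c(-0.70, -0.55, -0.65), -0.3, 4.5),
                 radius = 0.7)
  )
  ok <- c("flow_void", "pulsation_cloud", "contour_fusion", "tof_dropout")
  if (!all(artifacts %in% ok))
    stop("unknown artifact switch: ",
         paste(setdiff(artifacts, ok), collapse = ", "))
  spec <- list(
    shape = as.integer(rep_len(shape, 3)),
    voxel_mm = voxel_mm,
    brainstem = list(center = c0, semi = semi),
    csf = list(center = c0, semi = c(12.5, 11, 16)),
    vessels = vessels,
    nerves = nerves,
    ciss_mean = c(rest = 30, csf = 1000, brainstem = 320, nerve = 200,
                  vessel = 160),
    ciss_sd = c(rest = 10, csf = 30, brainstem = 25, nerve = 20,
                vessel = 20),
    tof_mean = c(rest = 25, csf = 60, brainstem = 120, nerve = 110,
                 vessel = 900),
    tof_sd = c(rest = 8, csf = 10, brainstem = 15, nerve = 15,
               vessel = 40),
    artifacts = artifacts,
    flow_void = list(vessels = c("basilar", "vertebral_l", "vertebral_r"),
                     fraction = 1),
    pulsation = list(center = NULL, radius = 6, amplitude = 180,
                     smooth_sigma = 0.8),
    contour = list(vessels = "pica_l"),
    dropout = list(vessels = c("aica_l", "aica_r", "sca_l", "sca_r"),
                   attenuation = 0.25),
    misalign = if (is.null(misalign)) rigid_transform() else misalign,
    noise_scale = noise_scale,
    seed = as.integer(seed)
  )
  spec <- modifyList(spec, list(...))
  radii <- vapply(spec$vessels, `[[`, numeric(1), "radius")
  small <- vapply(spec$vessels, `[[`, logical(1), "small")
  if (any(radii <= 0) || min(radii[!small]) <= max(radii[small]))
    stop("large-vessel radii must exceed small-vessel radii (all > 0)")
  class(spec) <- "phantom_spec"
  spec
}

#' Preset: "hard" phantom with all artifact classes enabled
#'
#' Flow voids in the basilar and both vertebral arteries, a pulsation
#' cloud around the basilar, contour fusion of the left PICA with the
#' brainstem, and TOF dropout of the small vessels (AICA/SCA).
#'
#' @param seed RNG seed.
#' @param ... passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
hard_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(artifacts = c("flow_void", "pulsation_cloud",
                             "contour_fusion", "tof_dropout"),
               seed = seed, ...)
}

# point on / near an axis-aligned ellipsoid surface along direction `dir`
# from the centre, offset outward by `clearance` mm
ellipsoid_surface_point <- function(center, semi, dir, clearance = 0) {
  u <- dir / sqrt(sum(dir^2))
  t <- 1 / sqrt(sum((u / semi)^2))
  center + (t + clearance) * u
}

# squared-normalized ellipsoid field at points (<= 1 means inside)
ellipsoid_field <- function(pts, center, semi) {
  ((pts[, 1] - center[1]) / semi[1])^2 +
    ((pts[, 2] - center[2]) / semi[2])^2 +
    ((pts[, 3] - center[3]) / semi[3])^2
}

# polyline control points -> segment matrix for cpp_polyline_dist
polyline_segments <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) stop("a tube needs at least 2 control points")
  cbind(pts[-n, , drop = FALSE], pts[-1, , drop = FALSE])
}

# resample a polyline at ~`by` mm arc-length steps (keeps endpoints)
densify_polyline <- function(pts, by = 0.8) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = max(2L, ceiling(total / by) + 1L))
  t(vapply(s, function(si) {
    i <- max(which(cum <= si + 1e-12))
    if (i >= nrow(pts)) return(pts[nrow(pts), ])
    f <- (si - cum[i]) / seglen[i]
    pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }, numeric(3)))
}

tube_distance_field <- function(ref, pts) {
  cpp_polyline_dist(dim(ref), ref$spacing, ref$origin,
                    as.vector(ref$direction), polyline_segments(pts),
                    maxdist = 4)
}

# Evaluate the phantom scene on the grid of `ref`. If `transform` is
# non-NULL the scene is rigidly displaced so that resampling the result
# through `transform` brings it back into alignment (used for the TOF
# volume). Returns the tissue code array (0 rest, 1 csf, 2 brainstem,
# 3 nerve, 4 vessel) and the individual masks.
phantom_scene <- function(ref, spec, transform = NULL) {
  pts <- grid_points(ref)
  tf_pts <- function(p) if (is.null(transform)) p else
    transform_points(transform, p)
  # ellipsoids are evaluated at back-transformed grid coordinates
  q <- if (is.null(transform)) pts else
    transform_points(invert_transform(transform), pts)
  d <- dim(ref)
  bs <- array(ellipsoid_field(q, spec$brainstem$center,
                              spec$brainstem$semi) <= 1, d)
  csf_outer <- array(ellipsoid_field(q, spec$csf$center,
                                     spec$csf$semi) <= 1, d)
  vessel_masks <- lapply(spec$vessels, function(v)
    array(tube_distance_field(ref, tf_pts(v$points)) <= v$radius, d))
  nerve_masks <- lapply(spec$nerves, function(nv)
    array(tube_distance_field(ref, tf_pts(nv$points)) <= nv$radius, d))
  tissue <- array(0L, d)
  tissue[csf_outer & !bs] <- 1L
  tissue[bs] <- 2L
  for (m in vessel_masks) tissue[m] <- 4L
  for (m in nerve_masks) tissue[m] <- 3L
  list(tissue = tissue, brainstem = bs, csf = csf_outer & !bs,
       vessel_masks = vessel_masks, nerve_masks = nerve_masks)
}

check_inside_grid <- function(spec) {
  extent <- (spec$shape - 1) * spec$voxel_mm
  tubes <- c(spec$vessels, spec$nerves)
  for (nm in names(tubes)) {
    r <- tubes[[nm]]$radius
    p <- tubes[[nm]]$points
    if (any(p < r - 0.5) || any(sweep(p, 2, extent - r + 0.5) > 0))
      stop(sprintf("structure '%s' extends outside the grid", nm))
  }
  invisible(TRUE)
}

#' Generate a paired CISS/TOF posterior-fossa phantom
#'
#' Produces the synthetic study substrate: a CISS-like volume
#' (hyperintense CSF, hypointense vessels/nerves/brainstem), a TOF-like
#' volume (hyperintense vessels over dark tissue) displaced by the spec's
#' misalignment transform, the four-sub-volume ground-truth label map
#' (vessels carry the CSF label 1), per-vessel ground truth
#' (centerlines, radii, relevant segments, voxel masks), and the applied
#' transform. Enabled artifact switches inject flow voids, a pulsation
#' cloud, contour fusion and TOF small-vessel dropout. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom`: list with elements `ciss`, `tof`,
#'   `truth_labels`, `vessels` (a `vessel_truth`), `transform`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_inside_grid(spec)
  ref <- volume(array(0, spec$shape),
                spacing = rep(spec$voxel_mm, 3))
  scene <- phantom_scene(ref, spec)
  identity_tf <- max(abs(spec$misalign$rotation - diag(3))) < 1e-12 &&
    max(abs(spec$misalign$translation)) < 1e-12
  scene_m <- if (identity_tf) scene else
    phantom_scene(ref, spec, transform = spec$misalign)

  truth <- labelmap(array(c(0L, 1L, 2L, 3L, 1L)[scene$tissue + 1L],
                          spec$shape), ref)
  vtruth <- build_vessel_truth(ref, spec, scene$vessel_masks)

  set.seed(spec$seed)
  ti <- as.vector(scene$tissue) + 1L
  ciss_dat <- spec$ciss_mean[ti] +
    spec$noise_scale * spec$ciss_sd[ti] * rnorm(length(ti))
  ciss <- volume_like(array(pmax(0, ciss_dat), spec$shape), ref)

  tm <- as.vector(scene_m$tissue) + 1L
  tof_mean_vox <- spec$tof_mean[tm]
  if ("tof_dropout" %in% spec$artifacts) {
    a <- spec$dropout$attenuation
    bg <- spec$tof_mean[["rest"]]
    for (nm in spec$dropout$vessels) {
      m <- as.vector(scene_m$vessel_masks[[nm]])
      tof_mean_vox[m] <- bg + a * (tof_mean_vox[m] - bg)
    }
  }
  tof_dat <- tof_mean_vox +
    spec$noise_scale * spec$tof_sd[tm] * rnorm(length(tm))
  tof <- volume_like(array(pmax(0, tof_dat), spec$shape), ref)

  csf_only <- scene$csf & scene$tissue != 4L & scene$tissue != 3L
  csf_mean <- spec$ciss_mean[["csf"]]
  csf_sd <- spec$noise_scale * spec$ciss_sd[["csf"]]
  if ("flow_void" %in% spec$artifacts)
    ciss <- inject_flow_void(ciss, vtruth, spec$flow_void$vessels,
                             fraction = spec$flow_void$fraction,
                             csf_mean = csf_mean, csf_sd = csf_sd,
                             seed = spec$seed + 101L)
  if ("pulsation_cloud" %in% spec$artifacts) {
    ctr <- spec$pulsation$center
    if (is.null(ctr)) {
      cl <- vtruth$basilar$centerline
      ctr <- cl[ceiling(nrow(cl) / 2), ]
    }
    ciss <- inject_pulsation_cloud(ciss, ctr, spec$pulsation$radius,
                                   spec$pulsation$amplitude,
                                   seed = spec$seed + 102L,
                                   smooth_sigma =
                                     spec$pulsation$smooth_sigma %||% 0.8)
  }
  if ("contour_fusion" %in% spec$artifacts)
    ciss <- inject_contour_fusion(ciss, vtruth, scene$brainstem,
                                  spec$contour$vessels,
                                  seed = spec$seed + 103L)

  structure(list(ciss = ciss, tof = tof, truth_labels = truth,
                 vessels = vtruth, transform = spec$misalign,
                 csf_only_mask = csf_only, brainstem_mask = scene$brainstem,
                 nerve_mask = scene$tissue == 3L, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, %d vessels, artifacts: %s\n",
              paste(dim(x$ciss), collapse = "x"), length(x$vessels),
              if (length(x$spec$artifacts)) paste(x$spec$artifacts,
                                                  collapse = ", ")
              else "none"))
  invisible(x)
}

# per-vessel ground truth: densified centerline, mask, and the
# assignment of mask voxels to their nearest centerline sample
build_vessel_truth <- function(ref, spec, vessel_masks) {
  out <- lapply(names(spec$vessels), function(nm) {
    v <- spec$vessels[[nm]]
    cl <- densify_polyline(v$points, by = 0.8)
    k <- nrow(cl)
    rel <- seq(max(1L, floor(v$relevant[1] * (k - 1)) + 1L),
               min(k, ceiling(v$relevant[2] * (k - 1)) + 1L))
    vessel_truth_entry(ref, nm, cl, v$radius, rel, v$small,
                       vessel_masks[[nm]])
  })
  names(out) <- names(spec$vessels)
  class(out) <- "vessel_truth"
  out
}

# nearest centerline sample per mask voxel (chunked distance matrix)
vessel_truth_entry <- function(ref, name, cl, radius, rel_idx, small,
                               mask) {
  lin <- which(mask)
  idx <- arrayInd(lin, dim(mask)) - 1L
  w <- world_from_index(ref, idx, check = FALSE)
  group <- integer(length(lin))
  chunk <- 20000L
  for (s in seq(1L, length(lin), by = chunk)) {
    e <- min(s + chunk - 1L, length(lin))
    d2 <- outer(rowSums(w[s:e, , drop = FALSE]^2), rowSums(cl^2), "+") -
      2 * (w[s:e, , drop = FALSE] %*% t(cl))
    group[s:e] <- max.col(-d2, ties.method = "first")
  }
  list(name = name, centerline = cl, radius = radius, relevant = rel_idx,
       small = small, mask = mask, lin = lin, group = group)
}

#' Serialize vessel ground truth to JSON
#'
#' Stores centerlines (world mm), radii, relevant-segment indices and the
#' small-vessel flag; voxel masks are rebuilt from the tube geometry on
#' load (boundary voxels may differ sub-voxel from the generator's).
#'
#' @param vessels a `vessel_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vessel_truth <- function(vessels, path) {
  stopifnot(inherits(vessels, "vessel_truth"))
  x <- lapply(vessels, function(v)
    list(centerline = v$centerline, radius = v$radius,
         relevant = v$relevant, small = v$small))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read vessel ground truth from JSON
#'
#' @param path path written by [write_vessel_truth()].
#' @param ref [volume()] supplying the grid on which voxel masks are
#'   rebuilt from the analytic tube geometry.
#' @return A `vessel_truth`.
#' @export
read_vessel_truth <- function(path, ref) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(x), function(nm) {
    v <- x[[nm]]
    cl <- matrix(unlist(v$centerline), ncol = 3)
    mask <- array(tube_distance_field(ref, cl) <= v$radius, dim(ref))
    vessel_truth_entry(ref, nm, cl, v$radius, as.integer(v$relevant),
                       isTRUE(v$small), mask)
  })
  names(out) <- names(x)
  class(out) <- "vessel_truth"
  out
}

#' Inject flow voids into large-vessel lumina
#'
#' Moving spins do not contribute to the CISS signal, so the lumen of a
#' large artery can appear CSF-bright instead of dark. Voxels within
#' `fraction` of the lumen radius of the selected vessels are replaced by
#' draws from the CSF intensity distribution; any outer shell beyond
#' `fraction * radius` is untouched. The default `fraction = 1` models
#' complete loss of vessel/CSF contrast, the worst and most consequential
#' form of the artifact in large arteries.
#'
#' @param ciss CISS [volume()].
#' @param vessels a `vessel_truth` from [generate_phantom()].
#' @param which names of affected vessels (must be large vessels).
#' @param fraction inner-radius fraction that loses vessel contrast.
#' @param csf_mean,csf_sd CSF intensity distribution; if `NULL`,
#'   estimated from the brightest quartile of `ciss`.
#' @param seed RNG seed for the replacement draws.
#' @return The modified [volume()].
#' @export
inject_flow_void <- function(ciss, vessels, which, fraction = 1,
                             csf_mean = NULL, csf_sd = NULL, seed = 1L) {
  stopifnot(is_volume(ciss), inherits(vessels, "vessel_truth"))
  if (length(which) == 0L) return(ciss)
  bad <- setdiff(which, names(vessels))
  if (length(bad)) stop("unknown vessel name: ", paste(bad, collapse = ", "))
  if (any(vapply(vessels[which], `[[`, logical(1), "small")))
    stop("flow voids apply to large vessels only")
  if (is.null(csf_mean)) {
    bright <- ciss$data[ciss$data > stats::quantile(ciss$data, 0.75)]
    csf_mean <- mean(bright)
    if (is.null(csf_sd)) csf_sd <- sd(bright)
  }
  if (is.null(csf_sd)) csf_sd <- 0
  dat <- ciss$data
  set.seed(seed)
  for (nm in which) {
    v <- vessels[[nm]]
    dist <- tube_distance_field(ciss, v$centerline)
    core <- array(dist <= fraction * v$radius, dim(ciss))
    n <- sum(core)
    dat[core] <- pmax(0, rnorm(n, csf_mean, csf_sd))
  }
  volume_like(dat, ciss)
}

#' Inject a pulsation "foggy cloud"
#'
#' CSF pulsation driven by the basilar pulse wave perturbs intensities in
#' a spherical neighbourhood: a low-pass-filtered random field (Gaussian
#' kernel, 1.2 voxel SD), scaled to `amplitude` and tapered towards the
#' sphere boundary, is added inside the sphere. Negative excursions reach
#' the hypointense vessel range, so thresholded CSF segmentation admits
#' spurious vessel-like voxels there.
#'
#' @param ciss CISS [volume()].
#' @param center world centre of the sphere (mm).
#' @param radius sphere radius (mm).
#' @param amplitude SD of the added perturbation (intensity units);
#'   0 leaves the volume unchanged.
#' @param seed RNG seed.
#' @param smooth_sigma Gaussian kernel SD of the low-pass filter, voxels.
#' @return The modified [volume()].
#' @export
inject_pulsation_cloud <- function(ciss, center, radius, amplitude,
                                   seed = 1L, smooth_sigma = 0.8) {
  stopifnot(is_volume(ciss))
  if (amplitude == 0) return(ciss)
  idx_c <- index_from_world(ciss, center)
  rad_vox <- ceiling(radius / min(ciss$spacing)) + 1L
  d <- dim(ciss)
  if (any(idx_c < 0) || any(idx_c > d - 1))
    stop("pulsation sphere centre lies outside the grid")
  lo <- pmax(0L, as.integer(floor(idx_c)) - rad_vox)
  hi <- pmin(d - 1L, as.integer(ceiling(idx_c)) + rad_vox)
  set.seed(seed)
  bd <- hi - lo + 1L
  noise <- array(rnorm(prod(bd)), bd)
  noise <- gauss_smooth3(noise, sigma = smooth_sigma)
  # distances of box voxels to the sphere centre
  w <- world_from_index(ciss, as.matrix(expand.grid(lo[1]:hi[1],
                                                    lo[2]:hi[2],
                                                    lo[3]:hi[3])),
                        check = FALSE)
  r2 <- array(rowSums(sweep(w, 2, center, "-")^2), bd)
  inside <- r2 <= radius^2
  taper <- pmax(0, 1 - sqrt(r2) / radius)
  field <- noise / sd(noise[inside]) * amplitude * sqrt(pmin(1, taper * 4))
  field[!inside] <- 0
  dat <- ciss$data
  sl <- list((lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L)
  dat[sl[[1]], sl[[2]], sl[[3]]] <-
    pmax(0, dat[sl[[1]], sl[[2]], sl[[3]]] + field)
  volume_like(dat, ciss)
}

# separable Gaussian smoothing of a 3D array (truncated kernel)
gauss_smooth3 <- function(a, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(a)
  for (axis in 1:3) {
    out <- array(0, d)
    wsum <- array(0, d)
    for (o in -r:r) {
      wi <- k[o + r + 1]
      src <- pmin(pmax(seq_len(d[axis]) + o, 1L), d[axis])
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[axis]] <- src
      out <- out + wi * a[idx[[1]], idx[[2]], idx[[3]]]
      wsum <- wsum + wi
    }
    a <- out / wsum
  }
  a
}

#' Inject contour fusion of a vessel with the brainstem
#'
#' Where a vessel runs on the brainstem surface, similar intensities make
#' the CSF/vessel boundary vanish: vessel voxels within one voxel of the
#' brainstem are given intensities drawn from the brainstem distribution
#' (estimated from `brainstem_mask`), so subsequent delineation absorbs
#' them into sub-volume 2.
#'
#' @param ciss CISS [volume()].
#' @param vessels a `vessel_truth`.
#' @param brainstem_mask logical array of brainstem voxels.
#' @param which names of affected vessels; each must touch the brainstem.
#' @param seed RNG seed.
#' @return The modified [volume()].
#' @export
inject_contour_fusion <- function(ciss, vessels, brainstem_mask, which,
                                  seed = 1L) {
  stopifnot(is_volume(ciss), inherits(vessels, "vessel_truth"))
  if (length(which) == 0L) return(ciss)
  bad <- setdiff(which, names(vessels))
  if (length(bad)) stop("unknown vessel name: ", paste(bad, collapse = ", "))
  check_congruent(brainstem_mask, ciss, "mask and volume")
  near_bs <- dilate6(brainstem_mask)
  mu <- mean(ciss$data[brainstem_mask])
  sdv <- sd(ciss$data[brainstem_mask])
  dat <- ciss$data
  set.seed(seed)
  for (nm in which) {
    touch <- vessels[[nm]]$mask & near_bs
    if (!any(touch))
      stop(sprintf("vessel '%s' does not touch the brainstem", nm))
    dat[touch] <- pmax(0, rnorm(sum(touch), mu, sdv))
  }
  volume_like(dat, ciss)
}

#' Attenuate small / in-plane vessels in a TOF volume
#'
#' Slow or in-plane flow makes small vessels inconsistently reproduced in
#' TOF angiography. Intensities of the selected vessels' voxels are pulled
#' towards the background level: `I' = bg + attenuation * (I - bg)`.
#'
#' @param tof TOF [volume()] aligned with the vessel truth.
#' @param vessels a `vessel_truth`.
#' @param which names of affected vessels.
#' @param attenuation value in `[0, 1]`; 1 leaves the volume unchanged,
#'   0 drops the segments to background.
#' @param background background intensity; default the median of `tof`.
#' @return The modified [volume()].
#' @export
tof_dropout <- function(tof, vessels, which, attenuation,
                        background = NULL) {
  stopifnot(is_volume(tof), inherits(vessels, "vessel_truth"),
            attenuation >= 0, attenuation <= 1)
  if (length(which) == 0L || attenuation == 1) return(tof)
  bad <- setdiff(which, names(vessels))
  if (length(bad)) stop("unknown vessel name: ", paste(bad, collapse = ", "))
  if (is.null(background)) background <- stats::median(tof$data)
  dat <- tof$data
  for (nm in which) {
    m <- vessels[[nm]]$mask
    dat[m] <- background + attenuation * (dat[m] - background)
  }
  volume_like(dat, tof)
}

#' Deterministic seed voxels for phantom segmentation
#'
#' Derives the seeds a user would click: for the CSF growing, the
#' CSF-only voxel deepest inside the cistern (found by iterated erosion);
#' for the TOF growing, the voxel nearest each vessel centerline's
#' midpoint.
#'
#' @param phantom a [generate_phantom()] result.
#' @return List with components `csf` and `tof` (0-based index matrices).
#' @export
phantom_seeds <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  m <- phantom$csf_only_mask
  prev <- m
  while (TRUE) {
    er <- prev & !dilate6(!prev)
    if (!any(er)) break
    prev <- er
  }
  lin <- which(prev)[1]
  csf_seed <- arrayInd(lin, dim(m)) - 1L
  ref <- phantom$ciss
  tof_seeds <- do.call(rbind, lapply(phantom$vessels, function(v) {
    mid <- v$centerline[ceiling(nrow(v$centerline) / 2), ]
    matrix(as.integer(round(index_from_world(ref, mid))), 1)
  }))
  list(csf = csf_seed, tof = tof_seeds)
}

#' Ground-truth artifact census of a phantom
#'
#' Reports, per vessel, which artifact classes the generator injected
#' (from the spec, not inferred from the images).
#'
#' @param phantom a [generate_phantom()] result.
#' @return Data frame with columns `vessel`, `flow_void`,
#'   `pulsation_cloud`, `contour_fusion`, `tof_dropout`.
#' @export
artifact_census <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  sp <- phantom$spec
  on <- function(cls, lst) (cls %in% sp$artifacts) &
    names(sp$vessels) %in% lst
  data.frame(
    vessel = names(sp$vessels),
    flow_void = on("flow_void", sp$flow_void$vessels),
    pulsation_cloud = ("pulsation_cloud" %in% sp$artifacts) &
      names(sp$vessels) %in% "basilar",
    contour_fusion = on("contour_fusion", sp$contour$vessels),
    tof_dropout = on("tof_dropout", sp$dropout$vessels),
    row.names = NULL
  )
}
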