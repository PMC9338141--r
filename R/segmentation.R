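#' Seeded 3D volume growing with an intensity corridor
#'
#' Grows from the seed voxels through all voxels whose intensity lies in
#' the inclusive range `[lower, upper]`, restricted to a bounding box.
#' This is the semi-automatic "volume growing" used to segment the CSF
#' cistern (with both thresholds) and the TOF vessels (lower threshold
#' only, see [segment_tof_vessels()]).
#'
#' @param vol a [volume()].
#' @param seeds integer matrix (n x 3) or vector of 0-based voxel indices;
#'   seeds whose intensity is out of range contribute nothing.
#' @param lower,upper inclusive intensity thresholds (`lower <= upper`).
#' @param bbox a [bounding_box()] restricting growth; default whole grid.
#' @param connectivity 6 (face neighbours, default) or 26.
#' @return Logical 3D array: the grown mask.
#' @export
region_grow <- function(vol, seeds, lower, upper = Inf, bbox = NULL,
                        connectivity = 6L) {
  stopifnot(is_volume(vol))
  if (lower > upper) stop("'lower' must not exceed 'upper'")
  if (!connectivity %in% c(6L, 26L))
    stop("'connectivity' must be 6 or 26")
  seeds <- as_seed_matrix(seeds, dim(vol))
  if (is.null(bbox)) bbox <- full_bbox(vol)
  check_bbox(bbox, dim(vol))
  bb <- as.integer(rbind(bbox$lo, bbox$hi))  # lo1,hi1,lo2,hi2,lo3,hi3
  mask <- cpp_region_grow(vol$data, dim(vol), seeds, lower, upper, bb,
                          as.integer(connectivity))
  array(mask, dim(vol))
}

as_seed_matrix <- function(seeds, d) {
  m <- if (is.matrix(seeds)) seeds else matrix(seeds, ncol = 3,
                                               byrow = TRUE)
  if (ncol(m) != 3L || nrow(m) < 1L)
    stop("'seeds' must be a non-empty set of voxel index triples")
  storage.mode(m) <- "integer"
  if (any(m < 0L) || any(m[, 1] >= d[1]) || any(m[, 2] >= d[2]) ||
      any(m[, 3] >= d[3]))
    stop("seed voxel index out of bounds")
  m
}

#' Extract vessels from a (reformatted) TOF volume
#'
#' Flowing blood is hyperintense in TOF, so a lower threshold alone limits
#' the growing process (`upper = Inf`). The returned mask carries the
#' sub-volume-1 tag so that TOF vessels share the label of the vascular
#' structures in the CSF sub-volume (see [merge_vessel_labels()]).
#'
#' @inheritParams region_grow
#' @param tof_in_ciss TOF [volume()] already reformatted onto the CISS grid.
#' @param lower inclusive lower intensity threshold.
#' @return Logical mask with attribute `label = 1`.
#' @export
segment_tof_vessels <- function(tof_in_ciss, seeds, lower, bbox = NULL,
                                connectivity = 6L) {
  mask <- region_grow(tof_in_ciss, seeds, lower, Inf, bbox, connectivity)
  attr(mask, "label") <- 1L
  mask
}

#' Assemble the four-sub-volume label map
#'
#' Labels are assigned with the priority nerves (3) > brainstem (2) >
#' CSF+vessels (1) > rest (0), so every voxel receives exactly one label.
#'
#' @param reference [volume()] supplying the grid geometry.
#' @param csf_mask,brainstem_mask,nerve_mask logical arrays congruent with
#'   `reference` (each may be `NULL` for empty).
#' @return A [labelmap()].
#' @export
assemble_labelmap <- function(reference, csf_mask = NULL,
                              brainstem_mask = NULL, nerve_mask = NULL) {
  stopifnot(is_volume(reference))
  d <- dim(reference)
  empty <- array(FALSE, d)
  if (is.null(csf_mask)) csf_mask <- empty
  if (is.null(brainstem_mask)) brainstem_mask <- empty
  if (is.null(nerve_mask)) nerve_mask <- empty
  for (m in list(csf_mask, brainstem_mask, nerve_mask))
    check_congruent(m, reference, "mask and reference")
  lab <- array(0L, d)
  lab[csf_mask] <- 1L
  lab[brainstem_mask] <- 2L
  lab[nerve_mask] <- 3L
  labelmap(lab, reference)
}

#' Merge TOF vessel voxels into an existing label map
#'
#' Voxels of the TOF vessel mask receive the CSF/vessel label 1; this may
#' reclaim voxels mislabelled as brainstem by contour fusion (a vessel
#' hugging the brainstem surface inherits brainstem-like intensities in
#' CISS). Cranial-nerve voxels (label 3) are never overwritten.
#'
#' @param labels a [labelmap()].
#' @param tof_vessel_mask logical array congruent with `labels`.
#' @return The updated [labelmap()].
#' @export
merge_vessel_labels <- function(labels, tof_vessel_mask) {
  stopifnot(is_labelmap(labels))
  check_congruent(tof_vessel_mask, labels, "mask and label map")
  lab <- labels$data
  take <- tof_vessel_mask & lab != 3
  lab[take] <- 1
  labelmap(lab, labels)
}

#' Emulate interactive brainstem delineation
#'
#' The brainstem is delineated starting from a reference mask (in phantom
#' work, the generator's ground truth) and extended into directly adjacent
#' voxels whose intensity is within `tol_sd` standard deviations of the
#' mask's mean intensity — the way a rater tracing the brainstem boundary
#' on CISS slices absorbs indistinguishable neighbouring voxels. This is
#' what mislabels a contour-fused vessel as brainstem.
#'
#' @param ciss CISS [volume()].
#' @param brainstem_mask logical array: the reference brainstem.
#' @param tol_sd intensity tolerance in SD units (default 3).
#' @param iterations dilation-absorption passes (default 2).
#' @return Logical array: the delineated brainstem mask.
#' @export
delineate_brainstem <- function(ciss, brainstem_mask, tol_sd = 3,
                                iterations = 2L) {
  stopifnot(is_volume(ciss))
  check_congruent(brainstem_mask, ciss, "mask and volume")
  mu <- mean(ciss$data[brainstem_mask])
  sdv <- sd(ciss$data[brainstem_mask])
  mask <- brainstem_mask
  for (it in seq_len(iterations)) {
    cand <- dilate6(mask) & !mask
    cand <- cand & abs(ciss$data - mu) <= tol_sd * sdv
    if (!any(cand)) break
    mask <- mask | cand
  }
  mask
}

# one 6-neighbourhood binary dilation step
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

#' Suppress unconfirmed vessel-like specks in the CSF sub-volume
#'
#' Pulsation of the basilar artery perturbs CSF intensities into the
#' hypointense vessel range ("foggy cloud"), producing scattered dark
#' voxels inside sub-volume 1 that render as spurious vessel fragments.
#' This cleanup demotes to label 0 every connected component of
#' vessel-range label-1 voxels that is both small (fewer than
#' `min_component` voxels) and unconfirmed by the TOF vessel mask —
#' an automated stand-in for the expert's manual label optimization.
#'
#' @param labels a [labelmap()].
#' @param vol the (fused) [volume()] the labels refer to.
#' @param tof_vessel_mask logical array of TOF-confirmed vessels, or
#'   `NULL` to rely on component size alone.
#' @param threshold intensity below which a label-1 voxel counts as
#'   vessel-like; default half the CSF mean of `vol`.
#' @param min_component minimum voxel count for an unconfirmed component
#'   to survive (default 50).
#' @return The cleaned [labelmap()].
#' @export
optimize_vessel_labels <- function(labels, vol, tof_vessel_mask = NULL,
                                   threshold = NULL, min_component = 50L) {
  stopifnot(is_labelmap(labels), is_volume(vol))
  check_congruent(labels, vol)
  if (is.null(threshold)) {
    csf_vals <- vol$data[labels$data == 1]
    bright <- csf_vals[csf_vals > stats::median(csf_vals)]
    threshold <- 0.5 * mean(bright)
  }
  dark <- labels$data == 1 & vol$data < threshold
  comp <- array(cpp_label_components(dark, dim(vol), 26L), dim(vol))
  lab <- labels$data
  if (max(comp) > 0) {
    sizes <- tabulate(comp[comp > 0])
    confirmed <- rep(FALSE, length(sizes))
    if (!is.null(tof_vessel_mask)) {
      check_congruent(tof_vessel_mask, labels, "mask and label map")
      hit <- unique(comp[tof_vessel_mask & comp > 0])
      confirmed[hit] <- TRUE
    }
    drop_ids <- which(sizes < min_component & !confirmed)
    if (length(drop_ids))
      lab[comp %in% drop_ids] <- 0
  }
  labelmap(lab, labels)
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical arrays of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 for two empty masks.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
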