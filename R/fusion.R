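#' Fit the TOF-to-CISS intensity inversion line
#'
#' The maximum signal values of the two volumes anchor a straight line
#' through `(0, max_ciss)` and `(max_tof, 0)`:
#' `line(v) = max_ciss - (max_ciss / max_tof) * v`.
#' Applied to TOF vessel intensities it inverts them — the brightest
#' flowing blood maps to the darkest value — and places them in the
#' hypointense range that vessels occupy in the CISS data.
#'
#' @param ciss,tof [volume()] objects with non-negative, non-constant
#'   intensities. `tof` is normally the reformatted TOF volume.
#' @param robust if `TRUE`, anchor at the 99.9th intensity percentiles
#'   instead of the literal maxima (guards against single hot voxels;
#'   mapped values below zero are later clamped).
#' @return Object of class `inversion_line` with elements `slope`,
#'   `intercept`, `max_ciss`, `max_tof`.
#' @export
fit_inversion_line <- function(ciss, tof, robust = FALSE) {
  stopifnot(is_volume(ciss), is_volume(tof))
  if (min(ciss$data) < 0 || min(tof$data) < 0)
    stop("intensities must be non-negative")
  if (min(ciss$data) == max(ciss$data) || min(tof$data) == max(tof$data))
    stop("degenerate input: constant volume")
  max_ciss <- if (robust) stats::quantile(ciss$data, 0.999, names = FALSE)
    else max(ciss$data)
  max_tof <- if (robust) stats::quantile(tof$data, 0.999, names = FALSE)
    else max(tof$data)
  if (max_tof <= 0)
    stop("degenerate input: TOF maximum is zero")
  structure(list(slope = -max_ciss / max_tof, intercept = max_ciss,
                 max_ciss = max_ciss, max_tof = max_tof,
                 robust = robust),
            class = "inversion_line")
}

#' @export
print.inversion_line <- function(x, ...) {
  cat(sprintf(
    "<inversion_line> line(v) = %.6g %+.6g v  (anchors: max_ciss = %.6g, max_tof = %.6g%s)\n",
    x$intercept, x$slope, x$max_ciss, x$max_tof,
    if (isTRUE(x$robust)) ", robust" else ""))
  invisible(x)
}

#' Evaluate an inversion line
#'
#' @param object an [fit_inversion_line()] result.
#' @param v TOF intensity values.
#' @param ... unused.
#' @return Mapped CISS-range values (not clamped).
#' @export
predict.inversion_line <- function(object, v, ...) {
  object$intercept + object$slope * v
}

#' Replace CISS values by inverted TOF values at vessel voxels
#'
#' For every voxel of the vessel mask the output value is
#' `line(tof_in_ciss)` clamped to be non-negative; all other voxels keep
#' their original CISS value bit-for-bit. The output inherits the CISS
#' grid geometry.
#'
#' @param ciss CISS [volume()].
#' @param tof_in_ciss TOF [volume()] reformatted onto the CISS grid.
#' @param vessel_mask logical array congruent with the grids.
#' @param line an [fit_inversion_line()] result.
#' @return The fused [volume()].
#' @export
apply_fusion <- function(ciss, tof_in_ciss, vessel_mask, line) {
  stopifnot(is_volume(ciss), is_volume(tof_in_ciss),
            inherits(line, "inversion_line"))
  check_congruent(ciss, tof_in_ciss)
  check_congruent(vessel_mask, ciss, "mask and volume")
  fused <- ciss$data
  fused[vessel_mask] <- pmax(0, predict(line, tof_in_ciss$data[vessel_mask]))
  volume_like(fused, ciss)
}

#' Full register-reformat-segment-invert-fuse composition
#'
#' Composes the fusion stages on already-registered inputs: reformat the
#' TOF volume onto the CISS grid through `transform`, grow the TOF vessel
#' mask, fit the inversion line, replace CISS values at vessel voxels, and
#' merge the vessel label into the sub-volume map.
#'
#' @param ciss CISS [volume()].
#' @param tof TOF [volume()] in its own grid.
#' @param transform [rigid_transform()] from CISS world to TOF world
#'   (e.g. from [register_rigid()]).
#' @param csf_mask,brainstem_mask,nerve_mask logical arrays on the CISS
#'   grid (see [assemble_labelmap()]).
#' @param tof_params list with the TOF growing parameters: `seeds`
#'   (0-based index triples), `lower` (threshold), optional `bbox`,
#'   `connectivity`.
#' @param robust_max passed to [fit_inversion_line()].
#' @return List with elements `fused` ([volume()]), `labels`
#'   ([labelmap()]), `tof_in_ciss`, `vessel_mask`, `line`.
#' @export
fuse_pipeline <- function(ciss, tof, transform = rigid_transform(),
                          csf_mask = NULL, brainstem_mask = NULL,
                          nerve_mask = NULL, tof_params,
                          robust_max = FALSE) {
  tof_in_ciss <- reformat(tof, transform, ciss)
  vessel_mask <- segment_tof_vessels(
    tof_in_ciss, tof_params$seeds, tof_params$lower,
    bbox = tof_params$bbox,
    connectivity = if (is.null(tof_params$connectivity)) 6L
      else tof_params$connectivity)
  line <- fit_inversion_line(ciss, tof_in_ciss, robust = robust_max)
  fused <- apply_fusion(ciss, tof_in_ciss, vessel_mask, line)
  labels <- assemble_labelmap(ciss, csf_mask, brainstem_mask, nerve_mask)
  labels <- merge_vessel_labels(labels, vessel_mask)
  list(fused = fused, labels = labels, tof_in_ciss = tof_in_ciss,
       vessel_mask = vessel_mask, line = line)
}
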