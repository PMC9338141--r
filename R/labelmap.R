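#' Four-class sub-volume label map
#'
#' Integer grid congruent with a reference volume encoding the four
#' sub-volumes used throughout the fusion workflow:
#' \describe{
#'   \item{0}{all remaining structures (sub-volume 4) — rendered fully
#'     transparent}
#'   \item{1}{CSF area including all vascular structures (sub-volume 1)}
#'   \item{2}{brainstem (sub-volume 2)}
#'   \item{3}{cranial nerves (sub-volume 3)}
#' }
#'
#' @param labels integer 3D array with values in `{0,1,2,3}`.
#' @param ref a [volume()] supplying the grid geometry.
#' @return Object of class `c("labelmap", "volume")`.
#' @export
labelmap <- function(labels, ref) {
  stopifnot(is_volume(ref))
  if (!all(dim(labels) == dim(ref)))
    stop("label grid shape does not match the reference volume")
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:3))
    stop("label values must be in {0, 1, 2, 3}")
  lm <- volume_like(array(as.double(labels), dim(labels)), ref)
  class(lm) <- c("labelmap", "volume")
  lm
}

#' @export
print.labelmap <- function(x, ...) {
  d <- dim(x)
  counts <- tabulate(as.vector(x$data) + 1L, nbins = 4L)
  cat(sprintf("<labelmap> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  rest: %d | CSF+vessels: %d | brainstem: %d | nerves: %d\n",
              counts[1], counts[2], counts[3], counts[4]))
  invisible(x)
}

#' @rdname labelmap
#' @param x object.
#' @export
is_labelmap <- function(x) inherits(x, "labelmap")
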