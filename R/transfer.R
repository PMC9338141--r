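#' Piecewise-linear colour/opacity transfer function
#'
#' Ordered control points mapping scalar intensity to RGBA; between
#' points all four channels are interpolated linearly, outside the range
#' the end values are held.
#'
#' @param intensity strictly increasing control-point intensities (>= 2
#'   points unless the function is identically transparent).
#' @param r,g,b colour channels in `[0, 1]` (recycled if scalar).
#' @param alpha opacities in `[0, 1]` (recycled if scalar).
#' @return Object of class `transfer_function` (a data frame).
#' @export
transfer_function <- function(intensity, r, g, b, alpha) {
  n <- length(intensity)
  df <- data.frame(intensity = as.numeric(intensity),
                   r = rep_len(as.numeric(r), n),
                   g = rep_len(as.numeric(g), n),
                   b = rep_len(as.numeric(b), n),
                   alpha = rep_len(as.numeric(alpha), n))
  if (n < 1L || any(diff(df$intensity) <= 0))
    stop("control-point intensities must be strictly increasing")
  if (any(df$alpha < 0 | df$alpha > 1))
    stop("opacity must lie in [0, 1]")
  if (any(df$alpha > 0) && n < 2L)
    stop("a non-transparent transfer function needs >= 2 control points")
  class(df) <- c("transfer_function", "data.frame")
  df
}

#' Evaluate a transfer function at intensity values
#'
#' @param tf a [transfer_function()].
#' @param v numeric intensities.
#' @return n x 4 matrix with columns r, g, b, alpha.
#' @export
tf_eval <- function(tf, v) {
  stopifnot(inherits(tf, "transfer_function"))
  out <- matrix(0, length(v), 4,
                dimnames = list(NULL, c("r", "g", "b", "alpha")))
  if (nrow(tf) == 1L) {
    out[, 1] <- tf$r; out[, 2] <- tf$g; out[, 3] <- tf$b
    out[, 4] <- tf$alpha
    return(out)
  }
  for (ch in 1:4) {
    y <- tf[[ch + 1L]]
    out[, ch] <- stats::approx(tf$intensity, y, xout = v, rule = 2)$y
  }
  out
}

#' Default per-sub-volume transfer functions
#'
#' Realizes the standard colour scheme: red for vessels (sub-volume 1,
#' opaque over the hypointense range and fading to fully transparent at
#' CSF-bright intensities so that bright CSF never obscures the scene),
#' light gray at moderate opacity for the brainstem (2), opaque yellow for
#' the cranial nerves (3), and complete transparency for all remaining
#' structures (0).
#'
#' The label-1 opacity plateau (0.2 per reference step) is chosen so that
#' a large vessel several voxels across saturates to strong red while a
#' sub-voxel rim stays faint; see the package vignette for the arithmetic.
#'
#' @param intensity_max top of the intensity range the functions span.
#'   Either a number or a [volume()], in which case the 99.9th intensity
#'   percentile is used (robust against isolated hot voxels, which would
#'   otherwise stretch the opaque range).
#' @return Named list of four [transfer_function()]s, names `"0".."3"`.
#' @export
default_transfer_functions <- function(intensity_max) {
  M <- if (is_volume(intensity_max))
    stats::quantile(intensity_max$data, 0.999, names = FALSE)
  else as.numeric(intensity_max)
  stopifnot(M > 0)
  list(
    "0" = transfer_function(c(0, M), r = 0, g = 0, b = 0, alpha = 0),
    "1" = transfer_function(c(0, 0.45 * M, 0.6 * M, M),
                            r = 1, g = 0, b = 0,
                            alpha = c(0.2, 0.2, 0, 0)),
    "2" = transfer_function(c(0, M), r = 0.82, g = 0.82, b = 0.82,
                            alpha = 0.18),
    "3" = transfer_function(c(0, M), r = 1, g = 0.9, b = 0.05,
                            alpha = 0.9)
  )
}

#' Write transfer functions to YAML
#'
#' @param tfs named list of [transfer_function()]s (names = label codes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfer_functions <- function(tfs, path) {
  x <- lapply(tfs, function(tf)
    lapply(seq_len(nrow(tf)), function(i) as.list(tf[i, ])))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read transfer functions from YAML
#'
#' @param path path written by [write_transfer_functions()].
#' @return Named list of [transfer_function()]s.
#' @export
read_transfer_functions <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- yaml::read_yaml(path)
  lapply(x, function(pts) {
    m <- do.call(rbind, lapply(pts, as.data.frame))
    transfer_function(m$intensity, m$r, m$g, m$b, m$alpha)
  })
}
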