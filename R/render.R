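#' Orthographic raycasting camera
#'
#' @param view length-3 viewing direction (rays travel along it; need not
#'   be normalized).
#' @param up approximate up vector, non-parallel to `view`.
#' @param center world point the viewing window is centred on; default
#'   `NULL` means the volume centre at render time.
#' @param window_mm physical extent (width, height) of the viewing window
#'   in mm; scalar is square.
#' @param size_px image size (width, height) in pixels; scalar is square.
#' @param step_mm ray sampling step in mm.
#' @param background background colour (RGB in `[0,1]`).
#' @return Object of class `camera`.
#' @export
camera <- function(view = c(0, 1, 0), up = c(0, 0, 1), center = NULL,
                   window_mm = 40, size_px = 512, step_mm = 0.4,
                   background = c(0, 0, 0)) {
  view <- as.numeric(view); up <- as.numeric(up)
  nv <- sqrt(sum(view^2)); nu <- sqrt(sum(up^2))
  if (nv == 0 || nu == 0) stop("degenerate camera: zero direction")
  view <- view / nv; up <- up / nu
  if (abs(sum(view * up)) >= 1 - 1e-9)
    stop("degenerate camera: 'view' and 'up' are parallel")
  if (step_mm <= 0) stop("'step_mm' must be positive")
  window_mm <- rep_len(as.numeric(window_mm), 2)
  size_px <- rep_len(as.integer(size_px), 2)
  right <- c(view[2] * up[3] - view[3] * up[2],
             view[3] * up[1] - view[1] * up[3],
             view[1] * up[2] - view[2] * up[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * view[3] - right[3] * view[2],
           right[3] * view[1] - right[1] * view[3],
           right[1] * view[2] - right[2] * view[1])
  structure(list(view = view, up = upv, right = right, center = center,
                 window_mm = window_mm, size_px = size_px,
                 step_mm = step_mm, background = as.numeric(background)),
            class = "camera")
}

#' Camera from azimuth/elevation angles
#'
#' Azimuth rotates the view direction in the axial (x, y) plane (0 looks
#' along +y, i.e. from anterior); elevation tilts it towards +z.
#'
#' @param azimuth_deg,elevation_deg view angles in degrees.
#' @param ... passed on to [camera()].
#' @return A [camera()].
#' @export
camera_angles <- function(azimuth_deg = 0, elevation_deg = 0, ...) {
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  view <- c(sin(az) * cos(el), cos(az) * cos(el), -sin(el))
  camera(view = view, ...)
}

#' Front-to-back alpha compositing of one ray
#'
#' `C <- C + (1 - A) * alpha_i * C_i`, `A <- A + (1 - A) * alpha_i`, with
#' early termination once `A >= 0.99`; the remaining transparency is
#' filled with the background colour.
#'
#' @param colors n x 3 matrix of sample colours (front first).
#' @param opacities length-n vector of sample opacities in `[0, 1]`.
#' @param background RGB background colour.
#' @return Length-3 RGB pixel colour.
#' @export
composite_ray <- function(colors, opacities, background = c(0, 0, 0)) {
  if (length(opacities) == 0L) return(as.numeric(background))
  colors <- matrix(colors, ncol = 3)
  stopifnot(nrow(colors) == length(opacities),
            all(opacities >= 0 & opacities <= 1))
  C <- c(0, 0, 0); A <- 0
  for (i in seq_along(opacities)) {
    C <- C + (1 - A) * opacities[i] * colors[i, ]
    A <- A + (1 - A) * opacities[i]
    if (A >= 0.99) break
  }
  C + (1 - A) * as.numeric(background)
}

#' Direct volume rendering with per-sub-volume transfer functions
#'
#' Casts one orthographic ray per pixel through the volume. At each step
#' the intensity is sampled trilinearly and the sub-volume label with
#' nearest-neighbour sampling; the label's transfer function converts the
#' intensity to colour and opacity, the opacity is weighted by the
#' label's partial-volume membership (trilinear sample of that label's
#' indicator volume — this suppresses the spurious dark rim that
#' interpolated intensities would otherwise paint along sub-volume
#' boundaries) and corrected for the step length
#' (`alpha' = 1 - (1 - alpha)^(step / reference_step)`), and the samples
#' are composited front to back (per-pixel early termination at
#' accumulated opacity 0.99). Deterministic for fixed inputs.
#'
#' @param vol [volume()] of intensities.
#' @param labels congruent [labelmap()].
#' @param tfs named list of [transfer_function()]s for labels `"0".."3"`
#'   (e.g. [default_transfer_functions()]).
#' @param cam a [camera()].
#' @param reference_step step length (mm) at which the transfer-function
#'   opacities are defined; default 0.4 (the CISS voxel size).
#' @return `height x width x 3` array of RGB values in `[0, 1]`, row 1 at
#'   the top of the image; attribute `camera` carries the resolved camera.
#' @export
render <- function(vol, labels, tfs, cam = camera(),
                   reference_step = 0.4) {
  stopifnot(is_volume(vol), is_labelmap(labels), inherits(cam, "camera"))
  check_congruent(vol, labels)
  center <- if (is.null(cam$center)) volume_center(vol) else cam$center
  nx <- cam$size_px[1]; ny <- cam$size_px[2]
  pitch <- cam$window_mm / cam$size_px
  sx <- (seq_len(nx) - 0.5 - nx / 2) * pitch[1]
  sy <- (ny / 2 - (seq_len(ny) - 0.5)) * pitch[2]  # row 1 = top
  px <- as.matrix(expand.grid(col = sx, row = sy))
  npix <- nrow(px)
  # ray start: window plane pushed back past the whole volume
  half_diag <- sqrt(sum((dim(vol) * vol$spacing)^2)) / 2
  base <- matrix(center, npix, 3, byrow = TRUE) +
    outer(px[, 1], cam$right) + outer(px[, 2], cam$up) -
    (half_diag + cam$step_mm) * matrix(cam$view, npix, 3, byrow = TRUE)
  n_steps <- ceiling(2 * (half_diag + cam$step_mm) / cam$step_mm) + 1L
  # march in index space: the world->index map is affine
  to_idx <- function(w) sweep(sweep(w, 2, vol$origin, "-") %*%
                                vol$direction, 2, vol$spacing, "/")
  idx <- to_idx(base)
  didx <- drop((cam$step_mm * cam$view) %*% vol$direction) / vol$spacing
  didx <- matrix(didx, npix, 3, byrow = TRUE)
  corr <- cam$step_mm / reference_step
  C <- matrix(0, npix, 3)
  A <- numeric(npix)
  lab_codes <- as.character(0:3)
  present <- lab_codes[vapply(lab_codes, function(lc)
    any(labels$data == as.numeric(lc)), logical(1))]
  # per-label indicator volumes for partial-volume membership weighting
  indicators <- lapply(setNames(present, present), function(lc)
    array(as.double(labels$data == as.numeric(lc)), dim(labels)))
  for (s in seq_len(n_steps)) {
    active <- A < 0.99
    if (!any(active)) break
    iv <- cpp_sample_trilinear(vol$data, dim(vol), idx, 0)
    il <- cpp_sample_nearest(labels$data, dim(labels), idx, 0)
    rgba <- matrix(0, npix, 4)
    for (lc in present) {
      pick <- il == as.numeric(lc)
      if (any(pick)) {
        tf <- tfs[[lc]]
        if (is.null(tf)) stop(sprintf("no transfer function for label %s",
                                      lc))
        rgba[pick, ] <- tf_eval(tf, iv[pick])
        memb <- cpp_sample_trilinear(indicators[[lc]], dim(labels),
                                     idx[pick, , drop = FALSE], 0)
        rgba[pick, 4] <- rgba[pick, 4] * memb
      }
    }
    a <- 1 - (1 - rgba[, 4])^corr
    w <- (1 - A) * a * active
    C <- C + w * rgba[, 1:3]
    A <- A + w
    idx <- idx + didx
  }
  C <- C + (1 - A) * matrix(cam$background, npix, 3, byrow = TRUE)
  img <- array(0, c(ny, nx, 3))
  for (ch in 1:3) img[, , ch] <- matrix(C[, ch], ny, nx, byrow = TRUE)
  attr(img, "camera") <- cam
  attr(img, "center") <- center
  img
}

#' Write a rendered image as 8-bit PNG
#'
#' @param img array from [render()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  out <- array(pmin(1, pmax(0, as.vector(img))), dim(img))
  png::writePNG(out, path)
  invisible(path)
}

#' Project world points into image pixel coordinates
#'
#' @param cam a [camera()] (with a resolved `center`).
#' @param points n x 3 matrix of world points (mm).
#' @param center world point the window is centred on.
#' @return Data frame with columns `row`, `col` (1-based pixel indices;
#'   may fall outside the image).
#' @export
project_points <- function(cam, points, center) {
  stopifnot(inherits(cam, "camera"))
  m <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  rel <- sweep(m, 2, center, "-")
  u <- rel %*% cam$right
  v <- rel %*% cam$up
  pitch <- cam$window_mm / cam$size_px
  data.frame(row = round(cam$size_px[2] / 2 - v / pitch[2] + 0.5),
             col = round(u / pitch[1] + cam$size_px[1] / 2 + 0.5))
}

#' Fraction of projected centreline points rendered as strong red
#'
#' Projects a vessel centreline into a rendered image and tests, for each
#' point, whether any pixel in its 3x3 neighbourhood is strongly red
#' (`R - max(G, B) >= red_margin`). The margin's default of 0.6 separates
#' the saturated red of a fully represented large vessel (accumulated
#' vessel opacity `1 - 0.8^n >= 0.77` for a lumen at least 2.6 mm across,
#' i.e. n >= 6.5 steps, under the default transfer functions) from the
#' faint partial-volume rim and pulsation fog left when a flow void has
#' erased the lumen; see the vignette for the compositing arithmetic.
#'
#' @param img rendered image from [render()].
#' @param centerline n x 3 matrix of world points (mm).
#' @param red_margin redness threshold.
#' @return Fraction in `[0, 1]` of centreline points visible as red.
#' @export
centerline_visibility <- function(img, centerline, red_margin = 0.6) {
  cam <- attr(img, "camera")
  center <- attr(img, "center")
  if (is.null(cam) || is.null(center))
    stop("'img' must carry its camera (render it with render())")
  pix <- project_points(cam, centerline, center)
  redness <- img[, , 1] - pmax(img[, , 2], img[, , 3])
  ny <- dim(img)[1]; nx <- dim(img)[2]
  hit <- vapply(seq_len(nrow(pix)), function(i) {
    rows <- pmin(pmax(pix$row[i] + (-1:1), 1), ny)
    cols <- pmin(pmax(pix$col[i] + (-1:1), 1), nx)
    max(redness[rows, cols]) >= red_margin
  }, logical(1))
  mean(hit)
}
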