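#' Joint intensity histogram of two volumes under a rigid transform
#'
#' Every voxel centre of the fixed grid is mapped through `transform` into
#' the moving volume and sampled trilinearly; sample points falling outside
#' the moving grid are discarded. Bin edges span each image's observed
#' `[min, max]` intensity range.
#'
#' @param fixed,moving [volume()] objects.
#' @param transform a [rigid_transform()] mapping fixed world points into
#'   moving world space (default identity).
#' @param bins number of bins per image (>= 2).
#' @param stride integer stride for subsampling the fixed grid.
#' @return Object of class `joint_histogram`: a list with the
#'   `bins x bins` count matrix and the bin ranges.
#' @export
joint_histogram <- function(fixed, moving, transform = rigid_transform(),
                            bins = 64L, stride = 1L) {
  stopifnot(is_volume(fixed), is_volume(moving))
  bins <- as.integer(bins)
  if (bins < 2L) stop("'bins' must be at least 2")
  pts <- grid_points(fixed, stride = stride)
  fvals <- as.vector(fixed$data[seq(1, dim(fixed)[1], by = stride),
                                seq(1, dim(fixed)[2], by = stride),
                                seq(1, dim(fixed)[3], by = stride)])
  mvals <- sample_trilinear(moving, transform_points(transform, pts),
                            outside = NA_real_)
  if (!any(is.finite(mvals)))
    stop("no overlap between the volumes under this transform")
  fr <- range(fixed$data)
  mr <- range(moving$data)
  counts <- cpp_joint_hist(fvals, mvals, bins, fr[1], fr[2], mr[1], mr[2])
  structure(list(counts = counts, fixed_range = fr, moving_range = mr,
                 bins = bins, n = sum(counts)),
            class = "joint_histogram")
}

#' Normalized mutual information of a joint histogram
#'
#' Studholme's overlap-invariant form
#' `NMI = (H_fixed + H_moving) / H_joint`, with entropies in nats computed
#' from the normalized histogram. Lies in `(1, 2]`; 2 is reached exactly
#' when the two intensity distributions determine each other.
#'
#' @param hist a [joint_histogram()], or a plain count matrix.
#' @return The similarity value.
#' @export
nmi <- function(hist) {
  counts <- if (inherits(hist, "joint_histogram")) hist$counts else
    as.matrix(hist)
  total <- sum(counts)
  if (total <= 0) stop("histogram has no counts")
  p <- counts / total
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  hf <- ent(rowSums(p))
  hm <- ent(colSums(p))
  if (hf == 0 || hm == 0)
    stop("degenerate input: a marginal entropy is zero (constant image)")
  (hf + hm) / ent(p)
}

#' Downsample a volume by integer block averaging
#'
#' Blocks of `factor^3` voxels are averaged; spacing grows by `factor` and
#' the origin moves to the centre of the first block, so world geometry is
#' preserved. Trailing voxels that do not fill a block are dropped.
#'
#' @param vol a [volume()].
#' @param factor integer >= 1.
#' @return A coarser [volume()].
#' @export
downsample_volume <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- dim(vol)
  nd <- d %/% factor
  if (any(nd < 2L)) stop("volume too small for this downsampling factor")
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor)]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(nd))
  a <- array(colMeans(a), nd)
  origin <- vol$origin +
    drop(vol$direction %*% ((factor - 1) / 2 * vol$spacing))
  volume(a, spacing = vol$spacing * factor, origin = origin,
         direction = vol$direction)
}

#' Rigid registration by normalized-mutual-information maximization
#'
#' Finds the 6-parameter rigid transform (3 Euler angles, 3 translations,
#' parameterized about the fixed volume's geometric centre) that maximizes
#' the normalized mutual information between the fixed volume and the
#' transformed moving volume. Optimization is derivative-free on a
#' three-stage coarse-to-fine pyramid: an exhaustive translation grid at
#' 4x downsampling (translation is sharply identifiable even on coarse
#' data), an exhaustive Euler-angle grid at 2x (rotation needs mid-scale
#' structure), and cyclic coordinate descent with golden-section line
#' searches at every stage, finishing with a full-resolution polish.
#'
#' @param fixed,moving [volume()] objects (CISS and TOF, respectively, in
#'   the intended workflow).
#' @param init initial [rigid_transform()]; the volumes must overlap under
#'   it. Defaults to identity (the sequences are acquired back-to-back, so
#'   initial alignment is approximate identity).
#' @param options list of tuning parameters: `bins` (histogram bins, 64;
#'   capped at 32 on downsampled levels, where histograms are sparse),
#'   `cycles` (coordinate-descent sweeps per stage, 3), `tol` (line-search
#'   tolerance, 0.01 units = 0.01 mm / 0.01 degrees), `polish` (extra
#'   full-resolution refinement on lightly smoothed copies, TRUE),
#'   `polish_sigma` (Gaussian SD of that smoothing in voxels, 1),
#'   `grid_mm` / `grid_deg` (half-widths of the exhaustive seeding
#'   grids, 4 mm / 9 degrees).
#' @return The optimal [rigid_transform()], with attributes `nmi` (final
#'   similarity), `nmi_init` (similarity at `init`) and `parameters`
#'   (Euler angles and translations about the fixed centre).
#' @export
register_rigid <- function(fixed, moving, init = rigid_transform(),
                           options = list()) {
  stopifnot(is_volume(fixed), is_volume(moving))
  opt <- modifyList(list(bins = 64L, cycles = 3L, tol = 0.01,
                         polish = TRUE, polish_sigma = 1,
                         grid_mm = 4, grid_deg = 9),
                    options)
  center <- volume_center(fixed)
  make_transform <- function(p)
    compose_transforms(init, euler_transform(p[1:3], p[4:6], center))

  # Precomputed per-level sampling cache: fixed values, fixed-grid world
  # points, and the moving volume's index-space affine.
  make_level <- function(fx, mv, stride = 1L) {
    pts <- grid_points(fx, stride = stride)
    # Deterministic sub-voxel jitter of the sample positions. Without it,
    # volumes sharing one grid geometry develop spurious NMI maxima at
    # zero rotation (all samples hit both lattices with one coherent
    # fractional offset — the well-known interpolation artifact of MI
    # registration); jittered samples remove that coherence for every
    # candidate transform alike.
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(760451L)
    jit <- matrix(runif(length(pts), -0.5, 0.5), ncol = 3)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    pts <- pts + sweep(jit, 2, fx$spacing, "*") %*% t(fx$direction)
    fvals <- sample_trilinear(fx, pts, outside = NA_real_)
    keep <- is.finite(fvals)
    # world -> moving-index affine, columns pre-scaled by 1/spacing
    Ds <- sweep(mv$direction, 2, mv$spacing, "/")
    list(fvals = fvals[keep], pts = pts[keep, , drop = FALSE], mv = mv,
         Ds = Ds, fr = range(fx$data), mr = range(mv$data))
  }
  level_nmi <- function(lev, p, bins) {
    tr <- make_transform(p)
    M <- t(tr$rotation) %*% lev$Ds
    off <- drop((tr$translation - lev$mv$origin) %*% lev$Ds)
    h <- cpp_affine_joint_hist(lev$mv$data, dim(lev$mv), lev$pts, M, off,
                               lev$fvals, bins, lev$fr[1], lev$fr[2],
                               lev$mr[1], lev$mr[2])
    if (sum(h) == 0) return(NA_real_)
    tryCatch(nmi(h), error = function(e) NA_real_)
  }

  # cyclic coordinate descent: golden-section line search per parameter
  refine <- function(cost, p, win, cycles, tol) {
    cur <- cost(p)
    for (cyc in seq_len(cycles)) {
      p_old <- p
      # alternate the sweep order so curved valleys are approached from
      # both ends of the parameter list
      for (j in if (cyc %% 2) 1:6 else 6:1) {
        w <- if (j <= 3) win[1] else win[2]
        if (w <= 0) next
        o <- stats::optimize(function(v) {
          q <- p; q[j] <- v; cost(q)
        }, c(p[j] - w, p[j] + w), tol = tol)
        if (o$objective <= cur) {
          p[j] <- o$minimum
          cur <- o$objective
        }
      }
      if (max(abs(p - p_old)) < tol) break
    }
    p
  }

  full2 <- make_level(fixed, moving, stride = 2L)
  # the polish level uses lightly smoothed copies: a 0.5-voxel Gaussian
  # removes the sub-voxel kinks the trilinear interpolant leaves in the
  # similarity surface without displacing its optimum
  full <- if (isTRUE(opt$polish)) {
    sm <- function(v) volume_like(gauss_smooth3(v$data, opt$polish_sigma), v)
    make_level(sm(fixed), sm(moving), stride = 1L)
  } else full2
  # fail early if there is no overlap at the initialization
  nmi_init <- level_nmi(full, rep(0, 6), opt$bins)
  if (is.na(nmi_init))
    stop("no overlap between the volumes at the initial transform")

  p <- rep(0, 6)
  # --- coarse level (4x): exhaustive translation seeding ---------------
  lev <- make_level(downsample_volume(fixed, 4), downsample_volume(moving, 4))
  bins_c <- min(opt$bins, 32L)  # sparse coarse histograms
  cost <- function(q) {
    v <- level_nmi(lev, q, bins_c)
    if (is.na(v)) 0 else -v
  }
  g <- opt$grid_mm
  tgrid <- as.matrix(expand.grid(tx = seq(-g, g, by = 2),
                                 ty = seq(-g, g, by = 2),
                                 tz = seq(-g, g, by = 2)))
  vals <- apply(tgrid, 1, function(d) cost(c(p[1:3], p[4:6] + d)))
  p[4:6] <- p[4:6] + tgrid[which.min(vals), ]
  p <- refine(cost, p, win = c(0, 1.2), cycles = opt$cycles, tol = opt$tol)

  # --- mid level (2x): exhaustive rotation seeding + joint refinement --
  lev <- make_level(downsample_volume(fixed, 2), downsample_volume(moving, 2))
  bins_m <- min(opt$bins, 32L)
  cost <- function(q) {
    v <- level_nmi(lev, q, bins_m)
    if (is.na(v)) 0 else -v
  }
  g <- opt$grid_deg
  rgrid <- as.matrix(expand.grid(rx = seq(-g, g, by = 3),
                                 ry = seq(-g, g, by = 3),
                                 rz = seq(-g, g, by = 3)))
  vals <- apply(rgrid, 1, function(d) cost(c(p[1:3] + d, p[4:6])))
  # rotation parameters are coupled; refine the best few grid cells and
  # keep the winner rather than trusting a single argmax
  cand <- order(vals)[1:3]
  best <- NULL
  best_val <- Inf
  for (k in cand) {
    pk <- refine(cost, c(p[1:3] + rgrid[k, ], p[4:6]),
                 win = c(2, 0.8), cycles = opt$cycles + 1L,
                 tol = opt$tol)
    vk <- cost(pk)
    if (vk < best_val) {
      best <- pk
      best_val <- vk
    }
  }
  p <- best

  # --- full resolution (stride-2 sampling, then stride-1 polish) -------
  cost <- function(q) {
    v <- level_nmi(full2, q, opt$bins)
    if (is.na(v)) 0 else -v
  }
  p <- refine(cost, p, win = c(2.5, 0.8), cycles = opt$cycles + 1L,
              tol = opt$tol)
  if (isTRUE(opt$polish)) {
    cost1 <- function(q) {
      v <- level_nmi(full, q, opt$bins)
      if (is.na(v)) 0 else -v
    }
    p <- refine(cost1, p, win = c(0.6, 0.25), cycles = opt$cycles + 2L,
                tol = opt$tol / 2)
  }
  nmi_final <- level_nmi(full, p, opt$bins)
  if (!is.na(nmi_final) && nmi_final < nmi_init) {
    # never report a transform worse than the starting point
    p <- rep(0, 6)
    nmi_final <- nmi_init
  }
  out <- make_transform(p)
  attr(out, "nmi") <- nmi_final
  attr(out, "nmi_init") <- nmi_init
  attr(out, "parameters") <- setNames(p, c("rx_deg", "ry_deg", "rz_deg",
                                           "tx_mm", "ty_mm", "tz_mm"))
  out
}

#' Resample a volume onto a reference grid through a rigid transform
#'
#' Every output voxel centre is mapped through `transform` into the moving
#' volume's world space and interpolated there. The output grid geometry
#' (shape, spacing, origin, direction) equals the reference's exactly, so
#' voxels of the output and the reference correspond one-to-one.
#'
#' @param moving [volume()] or [labelmap()] to resample.
#' @param transform a [rigid_transform()] (fixed world to moving world).
#' @param reference [volume()] supplying the output grid.
#' @param interpolation `"trilinear"` (default) or `"nearest"`; label maps
#'   always use nearest-neighbour.
#' @param outside fill value for points outside the moving grid.
#' @return A [volume()] (or [labelmap()]) on the reference grid.
#' @export
reformat <- function(moving, transform, reference,
                     interpolation = c("trilinear", "nearest"),
                     outside = 0) {
  stopifnot(is_volume(moving), is_volume(reference),
            inherits(transform, "rigid_transform"))
  interpolation <- match.arg(interpolation)
  if (is_labelmap(moving)) interpolation <- "nearest"
  pts <- transform_points(transform, grid_points(reference))
  vals <- if (interpolation == "trilinear")
    sample_trilinear(moving, pts, outside = outside)
  else sample_nearest(moving, pts, outside = outside)
  out <- volume_like(array(vals, dim(reference)), reference)
  if (is_labelmap(moving)) out <- labelmap(out$data, reference)
  out
}
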