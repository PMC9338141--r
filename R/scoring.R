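#' Coverage thresholds of the automated vessel-representation score
#'
#' The 0-5 observer scale ranks how completely a vessel is reproduced in
#' a visualization, from missing (0) through schematic (1), peripheral
#' fragments (2), proximal parts only (3) and the compression-relevant
#' parts (4) up to complete representation with branches (5). The
#' automated operationalization measures, along the ground-truth
#' centerline, the fraction of points whose local cross-section is
#' represented (at least `cross_section` of its voxels present) over the
#' whole vessel (`c_total`), the proximal half (`c_prox`) and the
#' relevant segment at the nerve contact (`c_rel`), and maps these
#' coverages to a score. All cut points are configurable here.
#'
#' @param cross_section fraction of cross-section voxels required for a
#'   centerline point to count as represented.
#' @param s5_total,s4_rel,s4_total,s3_prox,s2_total,s1_total coverage cut
#'   points of the decision table (see [vessel_score()]).
#' @return Named list of thresholds.
#' @export
score_thresholds <- function(cross_section = 0.5, s5_total = 0.95,
                             s4_rel = 0.95, s4_total = 0.6,
                             s3_prox = 0.8, s2_total = 0.25,
                             s1_total = 0.05) {
  list(cross_section = cross_section, s5_total = s5_total,
       s4_rel = s4_rel, s4_total = s4_total, s3_prox = s3_prox,
       s2_total = s2_total, s1_total = s1_total)
}

#' Score one vessel's representation on the 0-5 scale
#'
#' Decision table (first match wins, top to bottom):
#' \itemize{
#'   \item 5 — `c_total >= 0.95`: complete representation;
#'   \item 4 — `c_rel >= 0.95` and `c_total >= 0.6`: the
#'     compression-relevant parts are shown;
#'   \item 3 — `c_prox >= 0.8`: the proximal parts are shown;
#'   \item 2 — `c_total >= 0.25`: only peripheral fragments;
#'   \item 1 — `c_total >= 0.05`: the vessel can only be guessed;
#'   \item 0 — missing representation.
#' }
#' Ordered first-match evaluation makes the score monotone: adding
#' represented voxels can never lower it.
#'
#' @param mask logical array: the voxels in which the vessel is
#'   represented (e.g. from [vessel_representation()]).
#' @param truth a `vessel_truth` from [generate_phantom()].
#' @param vessel_name name of the vessel to score.
#' @param thresholds a [score_thresholds()] list.
#' @return Integer score in `0:5`, with attribute `coverage` carrying
#'   `c(total, prox, rel)`.
#' @export
vessel_score <- function(mask, truth, vessel_name,
                         thresholds = score_thresholds()) {
  stopifnot(inherits(truth, "vessel_truth"))
  if (!vessel_name %in% names(truth))
    stop(sprintf("unknown vessel '%s'", vessel_name))
  v <- truth[[vessel_name]]
  if (!all(dim(mask) == dim(v$mask)))
    stop("mask shape does not match the vessel truth grid")
  present <- mask[v$lin]
  k <- nrow(v$centerline)
  cov_pt <- vapply(seq_len(k), function(j) {
    sel <- v$group == j
    if (!any(sel)) return(NA_real_)
    mean(present[sel])
  }, numeric(1))
  rep_pt <- cov_pt >= thresholds$cross_section
  ok <- !is.na(rep_pt)
  c_total <- mean(rep_pt[ok])
  prox <- seq_len(ceiling(k / 2))
  c_prox <- mean(rep_pt[prox][ok[prox]])
  c_rel <- mean(rep_pt[v$relevant][ok[v$relevant]])
  if (is.nan(c_prox)) c_prox <- 0
  if (is.nan(c_rel)) c_rel <- 0
  th <- thresholds
  score <- if (c_total >= th$s5_total) 5L
    else if (c_rel >= th$s4_rel && c_total >= th$s4_total) 4L
    else if (c_prox >= th$s3_prox) 3L
    else if (c_total >= th$s2_total) 2L
    else if (c_total >= th$s1_total) 1L
    else 0L
  structure(score, coverage = c(total = c_total, prox = c_prox,
                                rel = c_rel))
}

#' Voxels in which vessels are visibly represented
#'
#' In the four-sub-volume model a vessel is shown wherever a sub-volume-1
#' voxel is hypointense (the vessel transfer function is opaque there and
#' transparent at CSF-bright values). The threshold defaults to
#' `frac = 0.5` of the CSF mean, estimated from the bright half of
#' sub-volume 1.
#'
#' @param vol [volume()] (original CISS or fused).
#' @param labels congruent [labelmap()].
#' @param frac fraction of the CSF mean below which a voxel counts as
#'   vessel-like.
#' @param csf_mean override for the CSF mean estimate.
#' @return Logical array.
#' @export
vessel_representation <- function(vol, labels, frac = 0.5,
                                  csf_mean = NULL) {
  stopifnot(is_volume(vol), is_labelmap(labels))
  check_congruent(vol, labels)
  if (is.null(csf_mean)) {
    csf_vals <- vol$data[labels$data == 1]
    if (length(csf_vals) == 0)
      stop("label map has no sub-volume-1 voxels")
    bright <- csf_vals[csf_vals > stats::median(csf_vals)]
    csf_mean <- mean(bright)
  }
  labels$data == 1 & vol$data < frac * csf_mean
}

#' Score every vessel before and after fusion
#'
#' @param pre,post lists with elements `volume` and `labels` describing
#'   the pre-fusion (original CISS + CISS-only labels) and post-fusion
#'   (fused volume + merged labels) states.
#' @param truth a `vessel_truth`.
#' @param case case identifier stored in the report.
#' @param thresholds a [score_thresholds()] list.
#' @param frac passed to [vessel_representation()].
#' @return A `score_report` data frame with columns `case`, `vessel`,
#'   `condition` (`"pre"`/`"post"`), `score`.
#' @export
score_case <- function(pre, post, truth, case = 1L,
                       thresholds = score_thresholds(), frac = 0.5) {
  for (cond in list(pre, post))
    if (is.null(cond$volume) || is.null(cond$labels))
      stop("each condition needs 'volume' and 'labels'")
  rows <- lapply(c(pre = "pre", post = "post"), function(cond) {
    x <- if (cond == "pre") pre else post
    mask <- vessel_representation(x$volume, x$labels, frac = frac)
    data.frame(case = case, vessel = names(truth), condition = cond,
               score = vapply(names(truth), function(nm)
                 as.integer(vessel_score(mask, truth, nm, thresholds)),
                 integer(1)),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("score_report", "data.frame")
  out
}

#' Combine score reports from several cases
#'
#' @param ... `score_report` data frames.
#' @return A single `score_report`.
#' @export
bind_reports <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("score_report", "data.frame")
  out
}

#' Cohort summary of vessel-representation scores
#'
#' Computes per-vessel and total means and population standard deviations
#' (divide by n) for each condition, the per-vessel mean improvement
#' (post minus pre), side-averaged improvements (left/right vessels of
#' the same artery pooled), and the percent increase of the total score.
#'
#' @param x a `score_report` (rows = vessel x condition x case scores).
#' @param ... unused.
#' @return Object of class `score_summary`: list with `per_vessel`,
#'   `total`, `side_averaged`, `percent_increase`.
#' @export
aggregate.score_report <- function(x, ...) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  vessels <- unique(x$vessel)
  per_vessel <- do.call(rbind, lapply(vessels, function(nm) {
    pre <- x$score[x$vessel == nm & x$condition == "pre"]
    post <- x$score[x$vessel == nm & x$condition == "post"]
    data.frame(vessel = nm, pre_mean = mean(pre), pre_sd = pop_sd(pre),
               post_mean = mean(post), post_sd = pop_sd(post),
               improvement = mean(post) - mean(pre), row.names = NULL)
  }))
  pre_all <- x$score[x$condition == "pre"]
  post_all <- x$score[x$condition == "post"]
  total <- data.frame(pre_mean = mean(pre_all), pre_sd = pop_sd(pre_all),
                      post_mean = mean(post_all),
                      post_sd = pop_sd(post_all))
  base <- sub("_(l|r|le|ri)$", "", per_vessel$vessel)
  side_averaged <- tapply(per_vessel$improvement, base, mean)
  structure(list(per_vessel = per_vessel, total = total,
                 side_averaged = side_averaged,
                 percent_increase =
                   percent_increase(total$pre_mean, total$post_mean)),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat("Vessel representation summary (0-5 scale)\n")
  print(transform(x$per_vessel,
                  pre_mean = round(pre_mean, 2),
                  pre_sd = round(pre_sd, 2),
                  post_mean = round(post_mean, 2),
                  post_sd = round(post_sd, 2),
                  improvement = round(improvement, 2)))
  cat(sprintf("Total: %.2f (%.2f) -> %.2f (%.2f), +%d%%\n",
              x$total$pre_mean, x$total$pre_sd, x$total$post_mean,
              x$total$post_sd, round(x$percent_increase)))
  invisible(x)
}

#' Percent increase of the total representation score
#'
#' `100 * (post - pre) / pre`; round the result to the nearest integer
#' for reporting.
#'
#' @param total_pre,total_post total mean scores before/after fusion.
#' @return The (unrounded) percent increase.
#' @export
percent_increase <- function(total_pre, total_post) {
  if (total_pre <= 0) stop("'total_pre' must be positive")
  100 * (total_post - total_pre) / total_pre
}

#' Reference cohort score table
#'
#' Published mean (population SD) vessel-representation scores of an
#' 80-case neurovascular-compression cohort, for slice-image (2D) and
#' direct-volume-rendered (3D) visualizations before (`pre`) and after
#' (`post`) CISS/TOF fusion, including the printed `total` row. Shipped
#' with the package as `inst/extdata/cohort_scores.csv`.
#'
#' @param visualization `"3d"` (default) or `"2d"`.
#' @return Data frame with columns `vessel`, `condition`, `mean`, `sd`.
#' @export
reference_cohort_scores <- function(visualization = c("3d", "2d")) {
  visualization <- match.arg(visualization)
  path <- system.file("extdata", "cohort_scores.csv",
                      package = "neurofuse", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df[df$visualization == visualization,
     c("vessel", "condition", "mean", "sd")]
}

#' Improvement arithmetic on a cohort mean table
#'
#' Given per-vessel mean scores before and after fusion (plus a `total`
#' row), computes per-vessel improvements, side-averaged improvements per
#' artery, and the percent increase of the total score (rounded to the
#' nearest integer for reporting, as well as raw).
#'
#' @param ref data frame as returned by [reference_cohort_scores()].
#' @return List with `per_vessel`, `side_averaged`, `percent_increase`
#'   (integer), `percent_increase_raw`.
#' @export
cohort_improvement <- function(ref = reference_cohort_scores("3d")) {
  need <- c("vessel", "condition", "mean")
  if (!all(need %in% names(ref))) stop("malformed cohort table")
  wide <- merge(ref[ref$condition == "pre", c("vessel", "mean")],
                ref[ref$condition == "post", c("vessel", "mean")],
                by = "vessel", suffixes = c("_pre", "_post"))
  tot <- wide[wide$vessel == "total", ]
  if (nrow(tot) != 1L) stop("cohort table needs a 'total' row")
  pv <- wide[wide$vessel != "total", ]
  pv$improvement <- pv$mean_post - pv$mean_pre
  base <- sub("_(l|r|le|ri)$", "", pv$vessel)
  side_averaged <- tapply(pv$improvement, base, mean)
  raw <- percent_increase(tot$mean_pre, tot$mean_post)
  list(per_vessel = pv, side_averaged = side_averaged,
       percent_increase = round(raw), percent_increase_raw = raw)
}
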