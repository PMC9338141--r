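#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage parameter of the register-segment-fuse-render-
#' score workflow, either from a YAML file or a named list, filling
#' defaults for everything unspecified. The defaults match the bundled
#' phantom's intensity scale (CSF around 1000, vessels around 160 in
#' CISS; TOF vessels around 900).
#'
#' @param x path to a YAML file, a named list of overrides, or `NULL`
#'   for pure defaults.
#' @return Object of class `run_config`.
#' @export
run_config <- function(x = NULL) {
  defaults <- list(
    seed = 1L,
    out_dir = "neurofuse_run",
    phantom = list(preset = "hard"),
    inputs = NULL,
    registration = list(skip = FALSE, options = list()),
    segmentation = list(lower = 90, upper = 1250, connectivity = 6L),
    tof_seg = list(lower = 400, connectivity = 6L),
    fusion = list(robust_max = FALSE),
    rendering = list(size_px = 256L, window_mm = 40, step_mm = 0.4,
                     azimuth = 0, elevation = 0),
    scoring = list(frac = 0.5),
    verbose = TRUE
  )
  over <- if (is.null(x)) list()
    else if (is.character(x)) yaml::read_yaml(x)
    else if (is.list(x)) x
    else stop("'x' must be a YAML path, a list, or NULL")
  cfg <- modifyList(defaults, over)
  if (!is.null(cfg$inputs)) {
    missing <- !vapply(cfg$inputs, file.exists, logical(1))
    if (any(missing))
      stop("input path(s) not found: ",
           paste(unlist(cfg$inputs[missing]), collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Execute the whole fusion workflow
#'
#' Runs, in order: phantom simulation (or input loading), rigid
#' registration of TOF to CISS, reformatting, CSF volume growing +
#' brainstem/nerve labelling, TOF vessel growing, inversion-line fusion,
#' label optimization, pre-/post-fusion rendering, and vessel scoring.
#' Every stage's parameters and output files (with MD5 content hashes)
#' are recorded in a JSON manifest; rerunning with the same config and
#' seed reproduces the hashes of all deterministic stages.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_all <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()[["elapsed"]]
  manifest <- list(seed = config$seed, stages = list())
  say <- function(...) if (isTRUE(config$verbose))
    message(sprintf("[neurofuse] %s", sprintf(...)))
  out_path <- function(f) file.path(config$out_dir, f)
  add_stage <- function(name, params, files, t0) {
    files <- files[file.exists(files)]
    manifest$stages[[name]] <<- list(
      stage = name, parameters = params,
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 2),
      files = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
    say("%s done (%.1f s)", name,
        manifest$stages[[name]]$wall_time_s)
  }

  # --- inputs: simulate a phantom or load volumes -------------------
  t0 <- proc.time()[["elapsed"]]
  phantom <- NULL
  if (!is.null(config$phantom)) {
    ph_args <- config$phantom
    preset <- ph_args$preset %||% "hard"
    ph_args$preset <- NULL
    ph_args$seed <- config$seed
    spec <- if (identical(preset, "hard"))
      do.call(hard_phantom_spec, ph_args)
    else do.call(phantom_spec, ph_args)
    phantom <- generate_phantom(spec)
    ciss <- phantom$ciss; tof <- phantom$tof
    write_volume(ciss, out_path("ciss.nii.gz"))
    write_volume(tof, out_path("tof.nii.gz"))
    write_volume(phantom$truth_labels, out_path("truth_labels.nii.gz"))
    write_vessel_truth(phantom$vessels, out_path("vessels.json"))
    write_transform(phantom$transform, out_path("true_transform.json"))
    add_stage("simulate",
              list(preset = preset, seed = config$seed,
                   artifacts = spec$artifacts),
              out_path(c("ciss.nii.gz", "tof.nii.gz",
                         "truth_labels.nii.gz", "vessels.json",
                         "true_transform.json")), t0)
  } else {
    if (is.null(config$inputs))
      stop("config needs either a 'phantom' block or 'inputs' paths")
    ciss <- read_volume(config$inputs$ciss)
    tof <- read_volume(config$inputs$tof)
    add_stage("load", config$inputs, character(), t0)
  }

  # --- registration --------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  transform <- if (isTRUE(config$registration$skip)) {
    if (!is.null(phantom)) phantom$transform else rigid_transform()
  } else {
    register_rigid(ciss, tof, options = config$registration$options)
  }
  write_transform(transform, out_path("transform.json"))
  add_stage("register",
            c(list(skip = isTRUE(config$registration$skip)),
              config$registration$options),
            out_path("transform.json"), t0)

  # --- segmentation --------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  seg <- config$segmentation
  if (!is.null(phantom)) {
    seeds <- phantom_seeds(phantom)
    csf_seed <- seg$seeds %||% seeds$csf
    tof_seeds <- config$tof_seg$seeds %||% seeds$tof
    brainstem_mask <- delineate_brainstem(ciss, phantom$brainstem_mask)
    nerve_mask <- phantom$nerve_mask
  } else {
    csf_seed <- as_seed_matrix(seg$seeds, dim(ciss))
    tof_seeds <- as_seed_matrix(config$tof_seg$seeds, dim(ciss))
    brainstem_mask <- read_volume(config$inputs$brainstem)$data > 0.5
    nerve_mask <- read_volume(config$inputs$nerves)$data > 0.5
  }
  csf_mask <- region_grow(ciss, csf_seed, seg$lower, seg$upper,
                          connectivity = seg$connectivity)
  labels_pre <- assemble_labelmap(ciss, csf_mask, brainstem_mask,
                                  nerve_mask)
  write_labels <- function(lm, f) write_volume(lm, out_path(f))
  write_labels(labels_pre, "labels_pre.nii.gz")
  add_stage("segment",
            list(lower = seg$lower, upper = seg$upper,
                 connectivity = seg$connectivity,
                 csf_seed = as.vector(csf_seed)),
            out_path("labels_pre.nii.gz"), t0)

  # --- fusion --------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  fused <- fuse_pipeline(ciss, tof, transform,
                         csf_mask = csf_mask,
                         brainstem_mask = brainstem_mask,
                         nerve_mask = nerve_mask,
                         tof_params = list(seeds = tof_seeds,
                                           lower = config$tof_seg$lower,
                                           connectivity =
                                             config$tof_seg$connectivity),
                         robust_max = isTRUE(config$fusion$robust_max))
  labels_post <- optimize_vessel_labels(fused$labels, fused$fused,
                                        fused$vessel_mask)
  write_volume(fused$tof_in_ciss, out_path("tof_in_ciss.nii.gz"))
  write_volume(fused$fused, out_path("fused.nii.gz"))
  write_labels(labels_post, "labels_post.nii.gz")
  jsonlite::write_json(
    list(slope = fused$line$slope, intercept = fused$line$intercept,
         max_ciss = fused$line$max_ciss, max_tof = fused$line$max_tof),
    out_path("inversion_line.json"), auto_unbox = TRUE, digits = NA)
  add_stage("fuse",
            list(tof_lower = config$tof_seg$lower,
                 robust_max = isTRUE(config$fusion$robust_max)),
            out_path(c("tof_in_ciss.nii.gz", "fused.nii.gz",
                       "labels_post.nii.gz", "inversion_line.json")), t0)

  # --- rendering -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  rnd <- config$rendering
  cam <- camera_angles(rnd$azimuth, rnd$elevation,
                       window_mm = rnd$window_mm, size_px = rnd$size_px,
                       step_mm = rnd$step_mm)
  tfs <- default_transfer_functions(ciss)
  img_pre <- render(ciss, labels_pre, tfs, cam)
  img_post <- render(fused$fused, labels_post, tfs, cam)
  write_image(img_pre, out_path("render_pre.png"))
  write_image(img_post, out_path("render_post.png"))
  add_stage("render", rnd,
            out_path(c("render_pre.png", "render_post.png")), t0)

  # --- scoring (needs ground truth) ---------------------------------
  if (!is.null(phantom)) {
    t0 <- proc.time()[["elapsed"]]
    report <- score_case(list(volume = ciss, labels = labels_pre),
                         list(volume = fused$fused, labels = labels_post),
                         phantom$vessels, case = config$seed,
                         frac = config$scoring$frac)
    write.csv(as.data.frame(report), out_path("scores.csv"),
              row.names = FALSE)
    summ <- aggregate(report)
    vis <- list(
      basilar_pre = centerline_visibility(
        img_pre, phantom$vessels$basilar$centerline),
      basilar_post = centerline_visibility(
        img_post, phantom$vessels$basilar$centerline))
    jsonlite::write_json(
      list(per_vessel = summ$per_vessel, total = summ$total,
           side_averaged = as.list(summ$side_averaged),
           percent_increase = summ$percent_increase,
           basilar_visibility = vis),
      out_path("score_summary.json"), auto_unbox = TRUE, digits = NA)
    add_stage("score", config$scoring,
              out_path(c("scores.csv", "score_summary.json")), t0)
  }

  manifest$wall_time_s <- round(proc.time()[["elapsed"]] - t_all, 2)
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("pipeline finished in %.1f s", manifest$wall_time_s)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
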