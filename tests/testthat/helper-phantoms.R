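# Shared phantom fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

clean_ph <- function() cached("clean", function()
  generate_phantom(phantom_spec(seed = 7)))

hard_ph <- function() cached("hard", function()
  generate_phantom(hard_phantom_spec(seed = 11)))

flow_void_ph <- function() cached("flow_void", function()
  generate_phantom(phantom_spec(seed = 3, artifacts = "flow_void")))

# pre/post pipeline products for a phantom (no registration; the phantom
# is generated aligned)
run_fusion_stages <- function(ph) {
  seeds <- phantom_seeds(ph)
  csf <- region_grow(ph$ciss, seeds$csf, 90, 1250)
  bs <- delineate_brainstem(ph$ciss, ph$brainstem_mask)
  labels_pre <- assemble_labelmap(ph$ciss, csf, bs, ph$nerve_mask)
  fus <- fuse_pipeline(ph$ciss, ph$tof, rigid_transform(), csf, bs,
                       ph$nerve_mask,
                       tof_params = list(seeds = seeds$tof, lower = 400))
  labels_post <- optimize_vessel_labels(fus$labels, fus$fused,
                                        fus$vessel_mask)
  list(csf = csf, brainstem = bs, labels_pre = labels_pre, fus = fus,
       labels_post = labels_post)
}

clean_stages <- function() cached("clean_stages", function()
  run_fusion_stages(clean_ph()))

hard_stages <- function() cached("hard_stages", function()
  run_fusion_stages(hard_ph()))

# rigid transform from a random axis-angle rotation + bounded translation
random_rigid <- function(max_angle_deg = 10, max_trans_mm = 5,
                         center = c(19, 19, 19)) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.2, 1) * max_angle_deg * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
             c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- rnorm(3); tr <- tr / sqrt(sum(tr^2)) * runif(1, 0.5, 1) *
    max_trans_mm
  rigid_transform(R, drop(center - R %*% center) + tr)
}
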