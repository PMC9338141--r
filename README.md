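# neurofuse

Voxel-level fusion of paired posterior-fossa MR volumes for the
assessment of neurovascular compression (NVC) — the pathological
contact between an artery and a cranial nerve at the brainstem surface
that underlies trigeminal neuralgia, hemifacial spasm and
glossopharyngeal neuralgia.

Two sequences see complementary halves of that anatomy. CISS (a
strongly T2-weighted cisternographic sequence) shows bright CSF against
dark nerves, vessels and brainstem, but large arteries are corrupted by
flow voids (the lumen turns CSF-bright and the vessel vanishes),
pulsation "clouds" around the basilar artery, and contour fusion of
vessels with the brainstem. TOF angiography shows flowing blood
brightly — large arteries are reliable — but drops small and in-plane
vessels. `neurofuse` registers the TOF volume rigidly onto the CISS
grid (normalized mutual information, derivative-free coarse-to-fine
search), grows the vessel and CSF sub-volumes by seeded thresholded
volume growing, and then performs the core operation: the two volumes'
maximum signal values anchor an **inversion line**

    line(v) = max_ciss − (max_ciss / max_tof) · v

through `(0, max_ciss)` and `(max_tof, 0)`, and every TOF-vessel
voxel's CISS value is replaced by `line(v_tof)`, clamped at zero. The
brightest flowing blood thereby becomes the darkest fused voxel,
landing exactly in the hypointense range vessels occupy in CISS. The
fused volume feeds an orthographic raycaster with one transfer function
per sub-volume (red vessels, yellow nerves, light-gray brainstem,
transparent remainder), and an automated 0–5 vessel-representation
score quantifies the before/after difference. A parametric
posterior-fossa phantom with ground-truth vessels and switchable
artifact injectors (flow void, pulsation cloud, contour fusion, TOF
dropout) makes every stage testable without patient data.

## Worked example

```r
library(neurofuse)

ph    <- generate_phantom(hard_phantom_spec(seed = 1))  # all artifacts on
seeds <- phantom_seeds(ph)

csf <- region_grow(ph$ciss, seeds$csf, lower = 90, upper = 1250)
bs  <- delineate_brainstem(ph$ciss, ph$brainstem_mask)
pre <- assemble_labelmap(ph$ciss, csf, bs, ph$nerve_mask)

fus  <- fuse_pipeline(ph$ciss, ph$tof, rigid_transform(), csf, bs,
                      ph$nerve_mask,
                      tof_params = list(seeds = seeds$tof, lower = 400))
post <- optimize_vessel_labels(fus$labels, fus$fused, fus$vessel_mask)

report <- score_case(list(volume = ph$ciss,   labels = pre),
                     list(volume = fus$fused, labels = post),
                     ph$vessels)
aggregate(report)
```

```
Vessel representation summary (0-5 scale)
       vessel pre_mean pre_sd post_mean post_sd improvement
1     basilar        0      0         5       0           5
2 vertebral_l        0      0         5       0           5
3 vertebral_r        0      0         5       0           5
4      pica_l        4      0         5       0           1
5      pica_r        4      0         5       0           1
6      aica_l        4      0         4       0           0
7      aica_r        2      0         2       0           0
8       sca_l        4      0         4       0           0
9       sca_r        4      0         4       0           0
Total: 2.44 (1.83) -> 4.33 (0.94), +77%
```

Flow voids had erased the basilar and both vertebrals before fusion
(score 0); after fusion all three are complete (score 5). The
contour-fused left PICA recovers its compression-relevant segment,
while the small vessels — dropped from TOF and partly degraded by the
pulsation cloud — are carried by the CISS information and do not
regress. `run_all(run_config(list(seed = 1)))` executes the same
workflow end to end (registration, rendering, scoring) and writes every
artifact with content hashes into a JSON manifest; a thin command-line
front end lives at `inst/cli/neurofuse`
(`simulate | register | segment-csf | segment-tof | fuse | render |
score | run-all`).

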