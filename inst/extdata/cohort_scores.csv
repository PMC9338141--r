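vessel,visualization,condition,mean,sd
basilar,2d,pre,3.62,1.65
basilar,2d,post,4.93,0.47
vertebral_r,2d,pre,3.66,1.57
vertebral_r,2d,post,4.59,0.85
vertebral_l,2d,pre,3.57,1.53
vertebral_l,2d,post,4.60,0.82
pica_r,2d,pre,2.93,2.05
pica_r,2d,post,3.53,2.11
pica_l,2d,pre,2.70,2.01
pica_l,2d,post,3.68,2.05
aica_r,2d,pre,4.00,1.54
aica_r,2d,post,3.04,1.90
aica_l,2d,pre,3.58,1.77
aica_l,2d,post,2.42,2.01
sca_r,2d,pre,3.89,1.56
sca_r,2d,post,3.98,1.56
sca_l,2d,pre,3.87,1.49
sca_l,2d,post,4.03,1.61
total,2d,pre,3.60,1.70
total,2d,post,3.88,1.74
basilar,3d,pre,3.40,1.76
basilar,3d,post,4.80,0.78
vertebral_r,3d,pre,2.13,1.49
vertebral_r,3d,post,4.49,0.93
vertebral_l,3d,pre,2.18,1.49
vertebral_l,3d,post,4.52,0.85
pica_r,3d,pre,2.19,1.87
pica_r,3d,post,3.60,1.96
pica_l,3d,pre,1.82,1.59
pica_l,3d,post,3.72,1.88
aica_r,3d,pre,3.06,1.79
aica_r,3d,post,3.59,1.74
aica_l,3d,pre,2.75,1.97
aica_l,3d,post,3.11,1.95
sca_r,3d,pre,2.92,1.66
sca_r,3d,post,3.66,1.55
sca_l,3d,pre,2.89,1.65
sca_l,3d,post,3.75,1.59
total,3d,pre,2.65,1.77
total,3d,post,3.96,1.59
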