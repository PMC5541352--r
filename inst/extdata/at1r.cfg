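# C-centred monoclinic GPCR scenario (low-symmetry preset)
[run]
seed = 1
outdir = at1r-run

[simulate]
scenario = at1r
n_images = 10
n_crystals = 5

[index]
n_voxels = 600
f_v = 0.3
sigma_2theta = 0.15
sigma_eta = 0.15

[evaluate]
tolerance_deg = 1
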