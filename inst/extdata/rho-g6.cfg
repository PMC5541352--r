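# I-centred cubic zeolite scenario (high-symmetry preset)
[run]
seed = 1
outdir = rho-g6-run

[simulate]
scenario = rho-g6
n_images = 5
n_crystals = 45

[index]
n_voxels = 300
f_v = 0.7
sigma_2theta = 0.3
sigma_eta = 0.3

[evaluate]
tolerance_deg = 1
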