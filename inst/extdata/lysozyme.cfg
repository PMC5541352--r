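# tetragonal hen egg-white lysozyme scenario
[run]
seed = 1
outdir = lysozyme-run

[simulate]
scenario = lysozyme
n_images = 10
n_crystals = 5

[index]
n_voxels = 400
f_v = 0.5
sigma_2theta = 0.15
sigma_eta = 0.15

[evaluate]
tolerance_deg = 1
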