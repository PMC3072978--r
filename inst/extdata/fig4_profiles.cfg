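# Secondary current distribution model, platinum electrodes in water:
# centerline field profiles above the insulator at the three study
# conductivities, plus the (sigma, V_app) sweep table.
model = secondary
sigma = 0.0005, 0.005, 0.05
V_app = 2.4, 2.7, 3.0, 3.2, 3.5
n_base = 32
grading = 3
out = fig4_sweep.csv
profile_out = centerline.csv
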