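# Parametric sweep of the non-dimensional primary channel model:
# probe field magnitude at (X = 0.5, Y = 1) over aspect ratio and
# relative insulator thickness.
model = primary
G = 0.1, 0.5, 1, 2
epsilon = 0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9
n_base = 48
grading = 3
out = fig3_sweep.csv
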