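# Worked micro-electroporation channel example: l = 10 um, h = 2 um,
# d = 100 nm => G = 0.2, epsilon = 0.01; dimensional fields follow from
# V_d = 0.5 V via E = E* V_d / l.
model = primary
G = 0.2
epsilon = 0.01
n_base = 48
out = discussion_channel.csv
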