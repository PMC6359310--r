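# Deep-target transcranial scenario: 7 mm skull, absorber 2.7 cm below the
# inner-skull surface, 0.25 inch flat detector coupled through 10 mm of
# water. All quantities carry explicit units.
preset: fig6
media: table1
h: 7 mm
d: 2.7 cm
k: 10 mm
r0: 1 mm
rd: 0.25 inch
T: 5 cm
fs: 50 MHz
n_freqs: 64
mesh_n: 100
max_reflections: 20
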