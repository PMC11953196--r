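# Example phantom specification: bumpy-border hole with speckle.
lumen_a_mm: 0.22
lumen_b_mm: 0.18
ring_width_mm: 0.10
bump_amplitude_mm: 0.03
bump_lobes: 8
speckle_sigma: 0.10
pixel_size_um: 10
seed: 1
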