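# Example experiment configuration: lab-style acquisition with a shorter
# scan. All sections override the named preset.
preset: lab_like
seed: 42
protocol:
  n_projections: 360
  photons_per_pixel: 1000
analysis:
  erode_px: 2
  reader_bias:
    reader1: 0.097
    reader2: 0.080
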