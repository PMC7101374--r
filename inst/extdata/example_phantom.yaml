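# Example phantom specification for `prlquant phantom --spec ...`.
# Geometry defaults to the 49 x 496 x 512 Spectralis-like protocol when the
# geometry block is omitted; all other keys map onto phantom_spec().
geometry:
  n_bscans: 16
  n_depth: 256
  n_ascans: 128
band_center_row: 150
band_thickness_px: 10
thickness_amplitude: 2.5
center_amplitude: 10
speckle_sigma: 0.15
disruptions:
  - { b: 5, x: 40, rb: 2.0, rx: 12 }
  - { b: 11, x: 90, rb: 1.5, rx: 9 }
shadows:
  - { x0: 60, x1: 66, factor: 0.5 }
cysts:
  - { b: 8, z: 100, x: 64, rb: 3, rz: 20, rx: 18 }
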