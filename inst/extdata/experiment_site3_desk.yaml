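# Desk-scale catchment experiment in the open preset world: an 11x11x11
# sampling cube (2 m side, 0.2 m spacing) centred 1.2 m above ground,
# reference snapshots at 0.2 m and 2.0 m, full-view and above-horizon
# comparisons, 96-pixel-wide panoramas.
scene: site3_like
grid:
  side_m: 2
  spacing_m: 0.2
  center: [0.0, 0.0, 1.2]
reference_heights_m: [0.2, 2.0]
mask_modes: [all, above]
backgrounds: [none]
threshold_fraction: 0.10
width: 96
seed: 1
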