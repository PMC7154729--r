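# Minimal end-to-end pipeline configuration: 2 animals per group on small
# sections, one counting frame each, coarse oxygen stage on one animal per
# group. Completes on one CPU in a few minutes.
seed: 1
n_per_group: 2
groups: [control, chronic_MS, OV_MS, OV, ligation]
section:
  width: 700
  height: 700
  frames: 1
recordings:
  enabled: true
oxygen:
  enabled: true
  frame_side: 80
  grid_um: 2
  demands: [rest, max]
stats:
  enabled: true
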