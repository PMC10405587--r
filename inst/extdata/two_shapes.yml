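# Example configuration: compare a 50 A sphere with a 20 x 400 A cylinder
seed: 1
output_dir: sasbead_out
q_grid: {min: 1.0e-3, max: 0.5, n_q: 400, spacing: log}
models:
  - name: sphere50
    n_points: 3000
    subunits:
      - kind: sphere
        dims: [50]
        delta_sld: 1
  - name: rod20x400
    n_points: 3000
    subunits:
      - kind: cylinder
        dims: [20, 400]
        delta_sld: 1
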