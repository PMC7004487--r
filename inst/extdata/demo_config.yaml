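# Demonstration pipeline configuration: two genotype-like groups of
# simulated taste-bud stacks, conditioned and quantified with the default
# chain, then compared by Kruskal-Wallis + Dunn.
seed: 7
out_dir: gustaquant_demo
# note: "y" must be quoted ("y": ...) or the YAML 1.1 parser reads it as TRUE
simulate:
  stack_shape: {z: 10, "y": 96, x: 96}
  bud_semiaxes_um: {x: 8.0, "y": 8.0, z: 4.5}
groups:
  WT:
    n_stacks: 2
  KO:
    n_stacks: 2
    fiber_density: 0.10
preprocess:
  ball_radius_px: 50
  median_radius_px: 2
quantify:
  reference_channel: P2X3
  colabel_channel: GFP
stats:
  test: kruskal_wallis
  dunn_adjust: none
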