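# Example run configuration: simulate a small 2D cohort of synthetic nuclei
# with peripherally placed chromosome territories.
#
#   Rscript inst/scripts/radialfish.R --config inst/extdata/example_scene.yaml
mode: simulate
out: example_out
seed: 1
scene:
  image_shape: [128, 128]
  pixel_size_xy: 0.2        # um / pixel
  nucleus_axes: [10.0, 6.5] # semi-axes, um
  nucleus_irregularity: 0.05
  dapi_level: 0.8
  probe_level: 1.0
  baseline_level: 0.15
  noise_sd: 0.05
  territory_radius: 1.0     # um
  territories_per_nucleus: 2
  radial_law: peripheral
  n_nuclei: 10
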