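# Example run configuration for the aopmeter CLI.
# aopmeter phantom  --config example-config.yaml
# aopmeter train    --config example-config.yaml --stage 1
# aopmeter train    --config example-config.yaml --stage 2 \
#                   --from-checkpoint out/stage1.ckpt
# aopmeter measure  --config example-config.yaml \
#                   --checkpoint out/stage2.ckpt \
#                   --images out/dataset/manifest.csv --out out/pred.csv
# aopmeter evaluate --config example-config.yaml \
#                   --predictions out/pred.csv \
#                   --manifest out/dataset/manifest.csv --out out/report
seed: 1
output_dir: out
data:
  n_standard: 60
  n_nonstandard: 60
  n_patients: 12
  target_size: [96, 96]
  ratios: [5, 2, 3]
phantom:
  image_width: 96
  image_height: 96
  speckle_strength: 0.25
  pixel_spacing_mm: 0.2
network:
  base_channels: 8
train:
  epochs: 10
  batch_size: 2
  sigma: 6
  n_triplets: 128
geometry:
  rule: max-angle
metrics:
  pixel_spacing_mm: 0.2
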