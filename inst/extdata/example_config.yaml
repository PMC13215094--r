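# Annotated example training configuration for `rclseg train --config ...`.
# Paths are resolved relative to the working directory.

manifest: data/train_manifest.tsv   # labelled manifest (id, residues, class, start, end)
architecture: unet                  # cnn | unet | bilstm
encoding: onehot                    # onehot | blosum | external_embedding
# embedding_path: data/esm2.embtxt  # required for external_embedding only
l_fixed: 512                        # fixed model length; U-Net needs a multiple of 2^depth
out_dir: runs/unet_onehot

model:                              # forwarded to model_config()
  base_channels: 16                 # width of the first level, doubling per level
  depth: 4                          # encoder levels; dropout defaults to 0.25 for unet
  kernel_size: 3

training:                           # forwarded to train_config()
  learning_rate: 0.001
  max_epochs: 50
  patience: 5                       # early stopping on validation F1
  batch_size: 32                    # use 4 for wide external embeddings
  val_fraction: 0.2
  seed: 1
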