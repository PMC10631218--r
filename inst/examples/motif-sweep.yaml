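# Desk-scale run on the planted-motif generator:
#   inst/cli/convboost sweep --config inst/examples/motif-sweep.yaml
recipe: genomic
data:
  generator:
    type: motif
    n_samples: 300
    length: 57
    mutation_prob: 0.15
    placement: random
split:
  train_frac: 0.8
  val_frac_of_train: 0.2
train:
  max_epochs: 30
  batch_size: 32
  patience: 10
sweep:
  max_blocks: 2
  select_on: validation
seed: 1
out_dir: convboost-run
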