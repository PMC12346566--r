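# Canonical diagnoser configuration (see ?diagnoser_config for field docs).
input_frames: 926
n_mfcc: 52
conv1_filters: 64
conv1_kernel: 5
conv2_filters: 128
conv2_kernel: 3
bn_momentum: 0.99
lstm1_units: 128
attention_units: 64
lstm2_units: 64
dense_units: 128
n_classes: 8
dropout: 0.5
l2: 0.001
lr: 0.001
beta1: 0.9
beta2: 0.999
epochs: 100
batch_size: 32
val_split: 0.2
patience: 10
variant: full
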