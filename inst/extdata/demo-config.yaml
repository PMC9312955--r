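# Demonstration run configuration: small synthetic benchmark.
# Flat key-value schema, version 1; unknown keys are rejected.
schema: 1
source: synthetic
seed: 1

synth_n_subjects: 2
synth_clips_per_class: 4
synth_n_channels: 4
synth_fs: 100
synth_clip_len_s: 60
synth_snr: 2
synth_sig_band_lo: 18
synth_sig_band_hi: 24
synth_burst_rate: 6

scalogram_n_scales: 32
scalogram_f_min: 2
scalogram_f_max: 50
scalogram_resize_h: 32
scalogram_resize_w: 64

model_patch_h: 8
model_patch_w: 8
model_embed_dim: 32
model_depth: 2
model_n_heads: 2
model_mlp_hidden: 64
model_dropout: 0.1

train_lr: 0.002
train_lr_decay: 0.92
train_warmup_epochs: 2
train_batch_size: 32
train_max_epochs: 6
train_val_fraction: 0.25
train_patience: 3
train_label_smoothing: 0.1
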