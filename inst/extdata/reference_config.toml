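# Reference calibration: published geometry plus free dimensions fixed by
# integer search against the parameter budgets (backbone 593,792; adapter +
# head 10,436; total 604,228).

[model]
C = 128
T_in = 200
D = 256
branch_specs = [[7, 1, 96], [5, 2, 96], [3, 4, 96]]
dw_multiplier = 4
D_t = 128
h = 8
L_t = 2
ffn_dim = 264
dw_kernel = 7
L_g = 2
g_dims = [32, 32]
D_s = 48
D_f = 64
gate_hidden = 32
D_e = 16
bottleneck_dim = 29
n_tasks = 2
head_hidden = 67
dropout = 0.1
knn_k = 8

[training]
lr0 = 1e-3
lr1 = 1e-4
batch_size = 16
max_epochs = 50
patience = 10
weight_decay = 1e-4
dropout = 0.1

[transfer]
max_epochs = 50
patience = 10
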