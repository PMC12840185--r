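# Desk-scale instance for CPU simulation studies (16 channels, small dims).

[model]
C = 16
T_in = 200
D = 32
branch_specs = [[7, 1, 8], [5, 2, 8], [3, 4, 8]]
dw_multiplier = 2
D_t = 32
h = 4
L_t = 1
ffn_dim = 64
dw_kernel = 7
L_g = 1
g_dims = [16]
D_s = 16
D_f = 32
gate_hidden = 16
D_e = 8
bottleneck_dim = 8
n_tasks = 2
head_hidden = 16
dropout = 0.1
knn_k = 4

[training]
batch_size = 16
max_epochs = 30
patience = 8

[transfer]
max_epochs = 12
patience = 6

[synthetic]
n_subjects = 60
epochs_per_subject = 50
C = 16
T_len = 200
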