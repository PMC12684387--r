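name	kcal_per_mol
6CUG	-1.79
UC6G	-1.72
6GUC	-1.56
UG6C	-1.24
6UUA	-1.10
6AUU	-0.92
UU6A	-0.83
UA6U	-0.73
6UUG	-0.69
6UU6	-0.46
UG6U	-0.32
UU6G	-0.32
66UU	-0.21
6GUU	-0.03
U66U	1.45
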