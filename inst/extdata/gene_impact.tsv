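group	impact	category	mean	se	mean_hom	se_hom
P493	moderate	missense	5.33	0.81	2.17	0.60
P493	moderate	in_frame_deletion	1.00	0.24	0.17	0.15
P493	moderate	in_frame_insertion	0	0	0	0
P493	moderate	total_moderate	6.33	0.81	2.34	0.51
P493	high	start_loss	0	0	0	0
P493	high	premature_stop	0.17	0.15	0	0
P493	high	frameshift	2.83	0.83	0.33	0.19
P493	high	truncation	1.00	0.41	0	0
P493	high	complete_deletion	11.83	7.04	0.67	0.61
P493	high	total_high	15.83	7.27	1.00	0.58
P493	high	total_high_excl_sv	3.00	0.85	0.33	0.19
P493	silent	silent	3.17	0.89	0.83	0.15
P787	moderate	missense	8.33	0.84	2.50	0.66
P787	moderate	in_frame_deletion	0.33	0.19	0.17	0.15
P787	moderate	in_frame_insertion	0	0	0	0
P787	moderate	total_moderate	8.66	0.90	2.67	0.65
P787	high	start_loss	0.33	0.19	0	0
P787	high	premature_stop	0.33	0.30	0	0
P787	high	frameshift	3.33	0.30	1.50	0.31
P787	high	truncation	2.17	0.55	0.17	0.15
P787	high	complete_deletion	22.00	19.18	0.17	0.15
P787	high	total_high	28.16	20.07	1.84	0.50
P787	high	total_high_excl_sv	4.00	0.62	1.50	0.31
P787	silent	silent	2.67	0.69	0.83	0.28
P995	moderate	missense	7.33	1.12	2.17	0.15
P995	moderate	in_frame_deletion	0.67	0.30	0	0
P995	moderate	in_frame_insertion	0	0	0	0
P995	moderate	total_moderate	8.00	1.13	2.17	0.15
P995	high	start_loss	0	0	0	0
P995	high	premature_stop	0.33	0.19	0.33	0.19
P995	high	frameshift	2.33	0.56	0.50	0.31
P995	high	truncation	1.50	0.74	0.50	0.31
P995	high	complete_deletion	1.00	0.62	0.67	0.61
P995	high	total_high	5.17	1.36	2.00	0.82
P995	high	total_high_excl_sv	2.67	0.56	0.83	0.44
P995	silent	silent	3.67	0.51	0.83	0.28
G900	moderate	missense	9.33	1.43	3.83	0.98
G900	moderate	in_frame_deletion	0.83	0.28	0	0
G900	moderate	in_frame_insertion	0.33	0.19	0	0
G900	moderate	total_moderate	10.49	1.45	3.83	0.98
G900	high	start_loss	0.17	0.15	0.17	0.15
G900	high	premature_stop	0.50	0.20	0	0
G900	high	frameshift	3.33	0.45	0.83	0.44
G900	high	truncation	0.67	0.45	0.50	0.46
G900	high	complete_deletion	0.17	0.15	0	0
G900	high	total_high	4.84	0.68	1.50	0.61
G900	high	total_high_excl_sv	4.00	0.33	1.00	0.41
G900	silent	silent	4.50	0.91	1.67	0.45
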