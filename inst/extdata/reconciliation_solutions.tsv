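## Published event-cost estimation output for the tropheine cichlid -
## Cichlidogyrus tanglegram: the two best adaptive-cost reconciliations for
## a fully resolved parasite tree and for a parasite tree with a basal
## polytomy. Event counts with their estimated (normalized) costs; the
## "retained" column records which solutions were accepted as biologically
## plausible (degenerate zero-switch / extreme-switch-cost solutions were
## rejected).
parasite_tree	rank	quality	total_cost	cospeciation	cost_cospeciation	sorting	cost_sorting	duplication	cost_duplication	switching	cost_switching	retained
resolved	1	0.0054	0.61	12	0.017	51	0.0040	15	0.013	0	0.97	no
resolved	2	0.04	9.53	11	0.25	33	0.074	12	0.20	4	0.47	yes
basal_polytomy	1	0.012	7.98	13	0.16	40	0.051	11	0.19	3	0.60	yes
basal_polytomy	2	0.018	0.032	10	0.000998	65	0.00017	17	0.00067	0	0.998	no
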