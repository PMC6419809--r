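n_drugs	10
n_clusters	2
attrs_per_cluster	3
family_universe	6
epsilon	0
fingerprint_length	32
sentences_per_drug	2
n_pairs	12
sim_sigma	0.05
seed	42
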