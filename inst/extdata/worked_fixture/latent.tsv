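drug_id	cluster
D001	1
D002	2
D003	1
D004	2
D005	1
D006	2
D007	1
D008	2
D009	1
D010	2
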