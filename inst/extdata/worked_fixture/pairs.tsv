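drug_a	drug_b	ddi	similarity
D002	D004	1	1.000000
D005	D007	1	1.000000
D002	D008	0	0.946159
D002	D010	1	1.000000
D001	D005	1	1.000000
D003	D007	1	0.990217
D003	D004	0	0.489091
D009	D008	0	0.484761
D006	D009	0	0.529892
D006	D007	0	0.569871
D010	D007	0	0.534381
D007	D008	0	0.516009
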