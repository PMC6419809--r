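ROOT	L1
ROOT	L2
L1	D001	drug
L2	D002	drug
L1	D003	drug
L2	D004	drug
L1	D005	drug
L2	D006	drug
L1	D007	drug
L2	D008	drug
L1	D009	drug
L2	D010	drug
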