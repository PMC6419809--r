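D001	pe001
D001	pe002
D001	pe003
D002	pe004
D002	pe005
D002	pe006
D003	pe001
D003	pe002
D003	pe003
D004	pe004
D004	pe005
D004	pe006
D005	pe001
D005	pe002
D005	pe003
D006	pe004
D006	pe005
D006	pe006
D007	pe001
D007	pe002
D007	pe003
D008	pe004
D008	pe005
D008	pe006
D009	pe001
D009	pe002
D009	pe003
D010	pe004
D010	pe005
D010	pe006
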