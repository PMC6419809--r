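D001	tg001
D001	tg002
D001	tg003
D002	tg004
D002	tg005
D002	tg006
D003	tg001
D003	tg002
D003	tg003
D004	tg004
D004	tg005
D004	tg006
D005	tg001
D005	tg002
D005	tg003
D006	tg004
D006	tg005
D006	tg006
D007	tg001
D007	tg002
D007	tg003
D008	tg004
D008	tg005
D008	tg006
D009	tg001
D009	tg002
D009	tg003
D010	tg004
D010	tg005
D010	tg006
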