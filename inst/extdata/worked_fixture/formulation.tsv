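D001	fo001
D001	fo002
D001	fo003
D002	fo004
D002	fo005
D002	fo006
D003	fo001
D003	fo002
D003	fo003
D004	fo004
D004	fo005
D004	fo006
D005	fo001
D005	fo002
D005	fo003
D006	fo004
D006	fo005
D006	fo006
D007	fo001
D007	fo002
D007	fo003
D008	fo004
D008	fo005
D008	fo006
D009	fo001
D009	fo002
D009	fo003
D010	fo004
D010	fo005
D010	fo006
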