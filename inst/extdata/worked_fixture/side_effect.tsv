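D001	se001
D001	se002
D001	se003
D002	se004
D002	se005
D002	se006
D003	se001
D003	se002
D003	se003
D004	se004
D004	se005
D004	se006
D005	se001
D005	se002
D005	se003
D006	se004
D006	se005
D006	se006
D007	se001
D007	se002
D007	se003
D008	se004
D008	se005
D008	se006
D009	se001
D009	se002
D009	se003
D010	se004
D010	se005
D010	se006
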