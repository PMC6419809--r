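D001	da001
D001	da002
D001	da003
D002	da004
D002	da005
D002	da006
D003	da001
D003	da002
D003	da003
D004	da004
D004	da005
D004	da006
D005	da001
D005	da002
D005	da003
D006	da004
D006	da005
D006	da006
D007	da001
D007	da002
D007	da003
D008	da004
D008	da005
D008	da006
D009	da001
D009	da002
D009	da003
D010	da004
D010	da005
D010	da006
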