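D001	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15
D002	16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31
D003	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15
D004	16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31
D005	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15
D006	16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31
D007	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15
D008	16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31
D009	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15
D010	16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31
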