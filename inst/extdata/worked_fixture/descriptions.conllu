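# drug_id = D001
1	D001	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg003	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se002	_	_	_	_	5	obj	_	_

# drug_id = D001
1	D001	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo001	_	_	_	_	3	obl	_	_

# drug_id = D002
1	D002	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg006	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se006	_	_	_	_	5	obj	_	_

# drug_id = D002
1	D002	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo004	_	_	_	_	3	obl	_	_

# drug_id = D003
1	D003	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg002	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se003	_	_	_	_	5	obj	_	_

# drug_id = D003
1	D003	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo002	_	_	_	_	3	obl	_	_

# drug_id = D004
1	D004	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg005	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se006	_	_	_	_	5	obj	_	_

# drug_id = D004
1	D004	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo004	_	_	_	_	3	obl	_	_

# drug_id = D005
1	D005	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg002	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se003	_	_	_	_	5	obj	_	_

# drug_id = D005
1	D005	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo002	_	_	_	_	3	obl	_	_

# drug_id = D006
1	D006	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg004	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se004	_	_	_	_	5	obj	_	_

# drug_id = D006
1	D006	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo006	_	_	_	_	3	obl	_	_

# drug_id = D007
1	D007	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg003	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se002	_	_	_	_	5	obj	_	_

# drug_id = D007
1	D007	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo002	_	_	_	_	3	obl	_	_

# drug_id = D008
1	D008	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg004	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se005	_	_	_	_	5	obj	_	_

# drug_id = D008
1	D008	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo005	_	_	_	_	3	obl	_	_

# drug_id = D009
1	D009	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg003	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se002	_	_	_	_	5	obj	_	_

# drug_id = D009
1	D009	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo001	_	_	_	_	3	obl	_	_

# drug_id = D010
1	D010	_	_	_	_	2	nsubj	_	Ent=1
2	binds	_	_	_	_	0	root	_	_
3	tg005	_	_	_	_	2	obj	_	Ent=2
4	and	_	_	_	_	5	cc	_	_
5	causes	_	_	_	_	2	conj	_	_
6	se006	_	_	_	_	5	obj	_	_

# drug_id = D010
1	D010	_	_	_	_	3	nsubj	_	Ent=1
2	is	_	_	_	_	3	aux	_	_
3	supplied	_	_	_	_	0	root	_	_
4	as	_	_	_	_	5	case	_	_
5	fo004	_	_	_	_	3	obl	_	_

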