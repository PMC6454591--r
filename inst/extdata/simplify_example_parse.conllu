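# sent_id = simplify_example
# text = Down-regulation of GENE_1 with small interfering RNA (siRNA) in pancreatic carcinoma cells resulted in the up-regulation of GENE_2 and GENE_3 expression
# note = synthetic hand-constructed Stanford-basic-style fixture parse
1	Down-regulation	_	_	_	_	13	nsubj	_	_
2	of	_	_	_	_	1	prep	_	_
3	GENE_1	_	_	_	_	2	pobj	_	_
4	with	_	_	_	_	1	prep	_	_
5	small	_	_	_	_	7	amod	_	_
6	interfering	_	_	_	_	7	amod	_	_
7	RNA	_	_	_	_	4	pobj	_	_
8	(siRNA)	_	_	_	_	7	appos	_	_
9	in	_	_	_	_	13	prep	_	_
10	pancreatic	_	_	_	_	12	amod	_	_
11	carcinoma	_	_	_	_	12	compound	_	_
12	cells	_	_	_	_	9	pobj	_	_
13	resulted	_	_	_	_	0	root	_	_
14	in	_	_	_	_	13	prep	_	_
15	the	_	_	_	_	16	det	_	_
16	up-regulation	_	_	_	_	14	pobj	_	_
17	of	_	_	_	_	16	prep	_	_
18	GENE_2	_	_	_	_	21	compound	_	_
19	and	_	_	_	_	18	cc	_	_
20	GENE_3	_	_	_	_	18	conj	_	_
21	expression	_	_	_	_	17	pobj	_	_
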