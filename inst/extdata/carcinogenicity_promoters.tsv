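attribute	class	mr_1_1	mr_1_2	mr_1_3	mr_2_1	mr_2_2	mr_2_3	mr_3_1	mr_3_2	mr_3_3	fr_1_1	fr_1_2	fr_1_3	fr_2_1	fr_2_2	fr_2_3	fr_3_1	fr_3_2	fr_3_3
1...(.......	smiles	0	0	0	0	0	0	0	0	0	1	1	1	1	0	1	1	0	1
2...(.......	smiles	1	1	1	0	0	0	1	1	1	0	0	0	0	0	0	0	0	0
2...1.......	smiles	1	1	0	0	0	1	1	1	0	0	0	0	0	0	0	0	0	0
C...1.......	smiles	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0
C...2.......	smiles	0	1	0	1	1	0	0	1	0	0	0	0	0	0	0	0	0	0
N...=.......	smiles	1	0	0	0	1	1	1	0	0	0	0	0	0	0	0	0	0	0
N...1.......	smiles	0	0	0	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0
HALO00000000	smiles	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0
BOND00000000	smiles	1	0	1	0	0	0	1	0	1	1	1	1	1	1	1	1	1	1
BOND10000000	smiles	0	0	0	0	0	0	0	0	0	1	1	0	1	1	1	0	0	0
BOND10100000	smiles	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0
C5......0...	graph	0	0	0	1	0	1	0	0	0	1	0	0	1	1	1	0	0	0
C6......0...	graph	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0
NNC-C...101.	graph	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	1	1	0
NNC-C...110.	graph	0	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	0	1
NNC-C...211.	graph	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
NNC-C...303.	graph	1	1	1	1	0	0	1	1	1	0	0	0	0	0	0	0	0	0
NNC-C...321	graph	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	1	0
NNC-O...101	graph	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	0
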