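pair	attribute	a1	a2	a3	b1	b2	b3
mutagenicity_vs_anticancer	1...........	+	+	+	+	+	+
mutagenicity_vs_anticancer	c...2.......	+	+	+	+	+	+
mutagenicity_vs_anticancer	c...(.......	+	+	+	+	+	+
mutagenicity_vs_anticancer	3...........	+	+	+	+	+	+
mutagenicity_vs_anticancer	C...........	+	+	+	+	+	+
mutagenicity_vs_anticancer	1...(.......	+	+	+	+	+	+
mutagenicity_vs_anticancer	C...1.......	+	+	+	+	+	+
mutagenicity_vs_anticancer	C...3.......	+	+	+	+	+	+
mutagenicity_vs_anticancer	Cl..(.......	+	+	+	+	+	+
mutagenicity_vs_anticancer	Cl..........	+	+	+	+	+	+
mutagenicity_vs_anticancer	c...........	+	+	+	-	-	-
mutagenicity_vs_anticancer	O...........	+	+	+	-	-	-
mutagenicity_vs_anticancer	O...(.......	+	+	+	-	-	-
mutagenicity_vs_anticancer	N...(.......	-	-	-	+	+	+
mutagenicity_vs_anticancer	++++N---O===	-	-	-	+	+	+
mutagenicity_vs_anticancer	NOSP11000000	-	-	-	+	+	+
mutagenicity_vs_anticancer	C...(.......	-	-	-	+	+	+
mutagenicity_vs_anticancer	C...C.......	-	-	-	+	+	+
mutagenicity_vs_bbb	1...........	+	+	+	+	+	+
mutagenicity_vs_bbb	BOND00000000	+	+	+	+	+	+
mutagenicity_vs_bbb	HALO00000000	+	+	+	+	+	+
mutagenicity_vs_bbb	NOSP10000000	+	+	+	+	+	+
mutagenicity_vs_bbb	1...(.......	+	+	+	+	+	+
mutagenicity_vs_bbb	++++CL--N===	+	+	+	+	+	+
mutagenicity_vs_bbb	-...........	+	+	+	+	+	+
mutagenicity_vs_bbb	=...(.......	+	+	+	+	+	+
mutagenicity_vs_bbb	C...1.......	+	+	+	+	+	+
mutagenicity_vs_bbb	BOND10000000	+	+	+	+	+	+
mutagenicity_vs_bbb	Cl..(.......	+	+	+	+	+	+
mutagenicity_vs_bbb	Cl..........	+	+	+	+	+	+
mutagenicity_vs_bbb	N...+.......	+	+	+	+	+	+
mutagenicity_vs_bbb	N...........	-	-	-	-	-	-
mutagenicity_vs_bbb	O...........	+	+	+	-	-	-
mutagenicity_vs_bbb	O...(.......	+	+	+	-	-	-
mutagenicity_vs_bbb	N...1.......	+	+	+	-	-	-
mutagenicity_vs_bbb	[...+.......	+	+	+	-	-	-
mutagenicity_vs_bbb	NOSP11000000	-	-	-	+	+	+
mutagenicity_vs_bbb	C...(.......	-	-	-	+	+	+
mutagenicity_vs_bbb	C...C.......	-	-	-	+	+	+
bbb_vs_anticancer	C...C.......	+	+	+	+	+	+
bbb_vs_anticancer	C...(.......	+	+	+	+	+	+
bbb_vs_anticancer	1...........	+	+	+	+	+	+
bbb_vs_anticancer	C...1.......	+	+	+	+	+	+
bbb_vs_anticancer	C...=.......	+	+	+	+	+	+
bbb_vs_anticancer	++++N---B2==	+	+	+	+	+	+
bbb_vs_anticancer	C...2.......	+	+	+	+	+	+
bbb_vs_anticancer	NOSP11000000	+	+	+	+	+	+
bbb_vs_anticancer	1...(.......	+	+	+	+	+	+
bbb_vs_anticancer	O...C.......	+	+	+	+	+	+
bbb_vs_anticancer	2...(.......	+	+	+	+	+	+
bbb_vs_anticancer	4...........	+	+	+	+	+	+
bbb_vs_anticancer	Cl..........	+	+	+	+	+	+
bbb_vs_anticancer	Cl..(.......	+	+	+	+	+	+
bbb_vs_anticancer	++++S---B2==	+	+	+	+	+	+
bbb_vs_anticancer	HALO01000000	+	+	+	+	+	+
bbb_vs_anticancer	++++F---B2==	+	+	+	+	+	+
bbb_vs_anticancer	++++F---N===	+	+	+	+	+	+
bbb_vs_anticancer	HALO10000000	+	+	+	+	+	+
bbb_vs_anticancer	N...4.......	+	+	+	+	+	+
bbb_vs_anticancer	++++CL--S===	+	+	+	+	+	+
bbb_vs_anticancer	(...........	-	-	-	-	-	-
bbb_vs_anticancer	O...........	-	-	-	-	-	-
bbb_vs_anticancer	O...(.......	-	-	-	-	-	-
bbb_vs_anticancer	5...........	-	-	-	-	-	-
bbb_vs_anticancer	C...5.......	-	-	-	-	-	-
bbb_vs_anticancer	++++Cl--B2==	+	+	+	-	-	-
bbb_vs_anticancer	F...(.......	+	+	+	-	-	-
bbb_vs_anticancer	++++F---Cl==	+	+	+	-	-	-
bbb_vs_anticancer	++++O---B2==	-	-	-	+	+	+
bbb_vs_anticancer	2...........	-	-	-	+	+	+
bbb_vs_anticancer	=...2.......	-	-	-	+	+	+
bbb_vs_anticancer	3...(.......	-	-	-	+	+	+
bbb_vs_anticancer	++++O---S===	-	-	-	+	+	+
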