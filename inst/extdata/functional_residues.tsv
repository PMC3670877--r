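consensus	AT1	AT2	MAS	effect	reference
224	D	D	D	conserved acidic position in all three receptors	curated
325	N	N	G	contacts Tyr4 of Ang II; Asn-to-Gly gain-of-activation in AT1; Gly in MAS	curated
336	L	L	L	photolabeled C-terminus contact in AT2	curated
512	K	K	I	basic contact for the Ang II C-terminus; hydrophobic in MAS	curated
517	F	F	F	natural-variant position conserved in all three and rhodopsin	curated
621	H	F	M	aromatic contact for Phe8 of Ang II; non-aromatic in MAS	curated
622	Q	H	-	adjacent to the aromatic contact; mutations alter ligand binding	curated
712	D	D	-	contacts Arg2 of Ang II; conserved in AT1/AT2 only	curated
723	Y	Y	T	displaced by Tyr4 of Ang II; Thr in MAS	curated
725	N	N	N	photolabeled C-terminus contact in AT1; not conserved in rhodopsin	curated
729	N	N	N	conserved polar position in all three receptors	curated
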