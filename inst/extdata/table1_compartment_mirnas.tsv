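rank	compartment	mirna	family	q	fold_change
1	TEB	mmu-miR-31	miR-31	0.009	10.76
2	TEB	mmu-miR-17*	miR-17	0.019	7.81
3	TEB	mmu-miR-18a	miR-17	0.005	4.72
4	TEB	mmu-miR-362-5p	miR-362	0.027	4.62
5	TEB	mmu-miR-19a	miR-17	0.007	3.27
1	duct	mmu-miR-184	miR-184	0.01	0.24
2	duct	mmu-miR-7g*	Let-7	0.028	0.3
3	duct	mmu-miR-1894-5p	miR-1894	0.027	0.37
4	duct	mmu-miR-346	miR-346	0.021	0.39
5	duct	mmu-miR-328	miR-328	0.024	0.41
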