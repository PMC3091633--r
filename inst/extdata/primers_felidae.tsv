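barcode_name	fwd_name	fwd	rev_name	rev	fragment_size	target_species
Pant	PantF	GTCATACGATTAACCCGG	PantR	TGCCATATTTTTATATTAACTGC	120	Panthera pardus
Unci	UnciF	CTAAACCTAGATAGTTAGCT	UnciR	CTCCTCTAGAGGGGTG	104	Uncia uncia
Prio	PrioF	CCTAAACTTAGATAGTTAATTTT	PrioR	GGATGTAAAGCACCGCC	94	Prionailurus bengalensis
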