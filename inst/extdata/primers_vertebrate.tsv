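barcode_name	fwd_name	fwd	rev_name	rev	fragment_size
COI-1	FF2d	TTCTCCACCAACCACAARGAYATYGG	FR1d	CACCTCAGGGTGTCCGAARAAYCARAA	655
COI-2H	LCO1490	GGTCAACAAATCATAAAGATATTGG	HCO2198	TAAACTTCAGGGTGACCAAAAAATCA	658
COI-2	C_VF1LFt1	WYTCAACCAAYCANAANGANATNGG	C_VR1LRt1	TARACTTCTGGRTGNCCNAANAANCA	658
COI-3	C_FishF1t1	TCRACYAAYCAYAAAGAYATYGGCAC	C_FishR1t1	ACYTCAGGGTGWCCGAARAAYCARAA	652
Uni-Minibar	UniMinibarF1	TCCACTAATCACAARGATATTGGTAC	UniMinibarR1	GAAAATCATAATGAAGGCATGAGC	130
MCB	mcb398	TACCATGAGGACAAATATCATTCTG	mcb869	CCTCCTAGTTTGTTAGGGATTGATCG	472
cytM	L14841	CCATCCAACATCTCAGCATGATGAAA	H15149	CCCCTCAGAATGATATTTGTCCTCA	359
16Sr	16Sar	CGCCTGTTTATCAAAAACAT	16Sbr	CCGGTCTGAACTCAGATCACGT	573
16Sr2	16Sa2	CGCCTGTTTACCAAAAACAT	16Sb	CCGGTCTGAACTCAGATCACGT	573
16Smam	16Smam1	CGGTTGGGGTGACCTCGGA	16Smam2	GCTGTTATCCCTAGGGTAACT	140
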