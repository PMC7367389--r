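# Precise annotation of the Dermacentor silvarum mitochondrial genome
# (reference MN347015; 1-based inclusive coordinates, End < Start wraps the
# origin; DNARegion=1 marks DNA-level annotations excluded from strand tiling)
Gene	Strand	Start	End	Length	DNARegion
tRNA-Met	(+)	1	67	67	0
ND2	(+)	68	1028	961	0
tRNA-Trp	(+)	1029	1091	63	0
tRNA-TyrAS	(+)	1092	1149	58	0
COI	(+)	1150	2686	1537	0
COII	(+)	2687	3359	673	0
tRNA-Lys	(+)	3360	3429	70	0
tRNA-Asp	(+)	3430	3491	62	0
ATP8/6	(+)	3492	4326	835	0
COIII	(+)	4327	5104	778	0
tRNA-Gly	(+)	5105	5171	67	0
ND3	(+)	5172	5511	340	0
tRNA-Ala	(+)	5512	5576	65	0
Intergenic	(+)	5577	5578	2	0
tRNA-Arg	(+)	5579	5640	62	0
tRNA-Asn	(+)	5641	5708	68	0
Intergenic	(+)	5709	5712	4	0
tRNA-Ser	(+)	5713	5769	57	0
tRNA-Glu	(+)	5770	5834	65	0
R2	(+)	5825	5987	163	1
HAS1	(+)	5835	9258	3424	0
tRNA-Ile	(+)	9259	9322	64	0
HAS2	(+)	9323	12930	3608	0
tRNA-Thr	(+)	12931	12991	61	0
tRNA-ProAS/ND6	(+)	12992	13503	512	0
Cytb	(+)	13504	14585	1082	0
tRNA-Ser	(+)	14586	14652	67	0
tRNA-LeuAS/CR2	(+)	14653	15023	371	0
CR2	(+)	14717	15023	307	1
tRNA-Cys	(+)	15024	15086	63	0
Intergenic	(+)	15087	15094	8	0
tRNA-Tyr	(-)	1090	1151	62	0
LAS1	(-)	1152	5984	4833	0
ND1	(-)	5985	6903	919	0
tRNA-Leu	(-)	6904	6964	61	0
16S rRNA	(-)	6965	8185	1221	0
tRNA-Val	(-)	8186	8247	62	0
12S rRNA	(-)	8248	8949	702	0
CR1	(-)	8950	9258	309	0
tRNA-IleAS	(-)	9259	9323	65	0
tRNA-Gln	(-)	9324	9390	67	0
R1	(-)	9391	9559	169	0
tRNA-Phe	(-)	9560	9620	61	0
ND5	(-)	9621	11275	1655	0
tRNA-His	(-)	11276	11341	66	0
ND4/4L	(-)	11342	12928	1587	0
tRNA-ThrAS	(-)	12929	12991	63	0
tRNA-Pro	(-)	12992	13055	64	0
LAS2	(-)	13056	14654	1599	0
tRNA-Leu	(-)	14655	14716	62	0
LAS3	(-)	14717	1089	1467	0
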