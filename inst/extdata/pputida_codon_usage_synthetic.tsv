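codon	aa	rel_freq
TAA	*	0.21
TAG	*	0.27
TGA	*	0.52
GCA	A	0.1094
GCC	A	0.4063
GCG	A	0.3437
GCT	A	0.1406
TGC	C	0.7429
TGT	C	0.2571
GAC	D	0.7429
GAT	D	0.2571
GAA	E	0.2414
GAG	E	0.7586
TTC	F	0.7429
TTT	F	0.2571
GGA	G	0.1094
GGC	G	0.4063
GGG	G	0.3437
GGT	G	0.1406
CAC	H	0.7429
CAT	H	0.2571
ATA	I	0.1667
ATC	I	0.619
ATT	I	0.2143
AAA	K	0.2414
AAG	K	0.7586
CTA	L	0.0773
CTC	L	0.2871
CTG	L	0.243
CTT	L	0.0994
TTA	L	0.0708
TTG	L	0.2224
ATG	M	1
AAC	N	0.7429
AAT	N	0.2571
CCA	P	0.1094
CCC	P	0.4062
CCG	P	0.3438
CCT	P	0.1406
CAA	Q	0.2414
CAG	Q	0.7586
AGA	R	0.0695
AGG	R	0.2183
CGA	R	0.0779
CGC	R	0.2893
CGG	R	0.2448
CGT	R	0.1002
AGC	S	0.2562
AGT	S	0.0887
TCA	S	0.0716
TCC	S	0.2662
TCG	S	0.2252
TCT	S	0.0921
ACA	T	0.1094
ACC	T	0.4062
ACG	T	0.3438
ACT	T	0.1406
GTA	V	0.1094
GTC	V	0.4062
GTG	V	0.3438
GTT	V	0.1406
TGG	W	1
TAC	Y	0.7429
TAT	Y	0.2571
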