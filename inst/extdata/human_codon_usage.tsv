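# Human codon usage, frequency per thousand codons (genome-wide)
codon	amino_acid	freq_per_thousand
AAA	K	24.4
AAC	N	19.1
AAG	K	31.9
AAT	N	17.0
ACA	T	15.1
ACC	T	18.9
ACG	T	6.1
ACT	T	13.1
AGA	R	12.2
AGC	S	19.5
AGG	R	12.0
AGT	S	12.1
ATA	I	7.5
ATC	I	20.8
ATG	M	22.0
ATT	I	16.0
CAA	Q	12.3
CAC	H	15.1
CAG	Q	34.2
CAT	H	10.9
CCA	P	16.9
CCC	P	19.8
CCG	P	6.9
CCT	P	17.5
CGA	R	6.2
CGC	R	10.4
CGG	R	11.4
CGT	R	4.5
CTA	L	7.2
CTC	L	19.6
CTG	L	39.6
CTT	L	13.2
GAA	E	29.0
GAC	D	25.1
GAG	E	39.6
GAT	D	21.8
GCA	A	15.8
GCC	A	27.7
GCG	A	7.4
GCT	A	18.4
GGA	G	16.5
GGC	G	22.2
GGG	G	16.5
GGT	G	10.8
GTA	V	7.1
GTC	V	14.5
GTG	V	28.1
GTT	V	11.0
TAA	*	1.0
TAC	Y	15.3
TAG	*	0.8
TAT	Y	12.2
TCA	S	12.2
TCC	S	17.7
TCG	S	4.4
TCT	S	15.2
TGA	*	1.6
TGC	C	12.6
TGG	W	13.2
TGT	C	10.6
TTA	L	7.7
TTC	F	20.3
TTG	L	12.9
TTT	F	17.6
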