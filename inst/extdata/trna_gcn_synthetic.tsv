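anticodon	copy_number
AGC	11
TGC	5
ACG	6
CCG	1
CCT	1
TCT	11
GTT	10
GTC	15
GCA	4
TTG	9
CTG	1
TTC	14
CTC	2
GCC	16
TCC	3
CCC	2
GTG	7
AAT	13
TAT	2
GAG	1
TAG	3
CAA	10
TAA	7
CTT	14
TTT	7
CAT	10
GAA	10
AGG	10
TGG	2
AGA	11
TGA	3
CGA	1
GCT	4
AGT	11
TGT	4
CGT	1
CCA	6
GTA	8
AAC	14
TAC	2
CAC	2
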