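codon	nte
AAA	0.55
AAC	1.1
AAG	1.3
AAT	0.6
ACA	0.7
ACC	1.05
ACG	0.45
ACT	1
AGA	0.85
AGC	0.55
AGG	0.4
AGT	0.5
ATA	0.35
ATC	1.1
ATG	1
ATT	1
CAA	1.15
CAC	1
CAG	0.6
CAT	0.8
CCA	1
CCC	0.45
CCG	0.3
CCT	0.7
CGA	0.12
CGC	0.35
CGG	0.25
CGT	0.75
CTA	0.5
CTC	0.45
CTG	0.4
CTT	0.55
GAA	1.2
GAC	1
GAG	0.65
GAT	0.85
GCA	0.8
GCC	0.95
GCG	0.45
GCT	1.25
GGA	0.5
GGC	0.95
GGG	0.4
GGT	1.2
GTA	0.55
GTC	1
GTG	0.9
GTT	1.15
TAC	1.05
TAT	0.6
TCA	0.7
TCC	1
TCG	0.45
TCT	1.1
TGC	0.7
TGG	0.9
TGT	0.75
TTA	0.8
TTC	1.1
TTG	1.2
TTT	0.65
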