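# Amino acid background compositions (renormalized at load).
# blosum62: marginal residue frequencies underlying the BLOSUM62 matrix.
# swissprot: UniProtKB/Swiss-Prot release composition statistics.
# pf: Pfam full-alignment residue composition.
aa	blosum62	swissprot	pf
A	0.074	0.0826	0.0853
C	0.025	0.0137	0.0145
D	0.054	0.0546	0.0576
E	0.054	0.0674	0.0655
F	0.047	0.0386	0.0405
G	0.074	0.0708	0.0735
H	0.026	0.0227	0.0222
I	0.068	0.0593	0.0593
K	0.058	0.0582	0.0583
L	0.099	0.0965	0.0935
M	0.025	0.0241	0.0236
N	0.045	0.0406	0.0423
P	0.039	0.0473	0.0443
Q	0.034	0.0393	0.0356
R	0.052	0.0553	0.0519
S	0.057	0.0660	0.0641
T	0.051	0.0535	0.0548
V	0.073	0.0687	0.0734
W	0.013	0.0110	0.0131
Y	0.032	0.0292	0.0301
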