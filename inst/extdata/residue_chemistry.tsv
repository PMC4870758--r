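# Per-residue side-chain chemistry driving the substitution classifier.
# heavy_atoms: non-hydrogen side-chain atom count (glycine = 0).
# polarity_class: nonpolar | polar | positive | negative (histidine counted positive).
code	heavy_atoms	polarity_class	is_cysteine	is_proline
G	0	nonpolar	0	0
A	1	nonpolar	0	0
S	2	polar	0	0
C	2	polar	1	0
T	3	polar	0	0
V	3	nonpolar	0	0
P	3	nonpolar	0	1
L	4	nonpolar	0	0
I	4	nonpolar	0	0
M	4	nonpolar	0	0
N	4	polar	0	0
D	4	negative	0	0
Q	5	polar	0	0
E	5	negative	0	0
K	5	positive	0	0
H	6	positive	0	0
R	7	positive	0	0
F	7	nonpolar	0	0
Y	8	polar	0	0
W	10	nonpolar	0	0
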