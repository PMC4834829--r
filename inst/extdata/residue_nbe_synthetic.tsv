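# Synthetic per-residue short+medium-range non-bonded energy table
# (arbitrary energy units, one value per one-letter amino-acid code).
# These values are a constructed stand-in scaled with side-chain heavy-atom
# count and polarizability; they are NOT measured reference data. Replace
# with your own two-column table (code, value) to use published energies.
A	-5.1
R	-10.1
N	-7.2
D	-7.0
C	-6.3
Q	-8.3
E	-8.1
G	-4.2
H	-9.0
I	-8.3
L	-8.4
K	-8.9
M	-8.7
F	-10.2
P	-6.5
S	-5.6
T	-6.6
W	-12.6
Y	-10.9
V	-7.3
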