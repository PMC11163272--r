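# RNA nearest-neighbor Watson-Crick stack free energies, dG37 in kcal/mol.
# Parameter set: Xia et al. (1998) Biochemistry 37:14719-14735 (Turner lab).
# 'stack' is the 5'->3' dinucleotide step on one strand of the duplex,
# paired with its Watson-Crick complement on the other strand; by duplex
# symmetry dG(XY) = dG(revcomp(XY)), so all 16 steps map to 10 unique values.
stack	dg37
AA	-0.93
AC	-2.24
AG	-2.08
AU	-1.10
CA	-2.11
CC	-3.26
CG	-2.36
CU	-2.08
GA	-2.35
GC	-3.42
GG	-3.26
GU	-2.24
UA	-1.33
UC	-2.35
UG	-2.11
UU	-0.93
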