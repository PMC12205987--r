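# Nearest-neighbor helix-propagation (stacking) free energies for RNA
# Watson-Crick dinucleotides at 37 C, kcal/mol. Entry XY is the stack of
# the 5'-XY-3' dinucleotide on the target strand paired with its full
# complement; by duplex symmetry dg37(XY) == dg37(revcomp(XY)).
# Values: canonical Watson-Crick nearest-neighbor set (Xia et al. 1998 /
# Turner 2004 parameters, as distributed with ViennaRNA's
# rna_turner2004.par). Edit this file to substitute another published
# parameter set; all 16 dinucleotides must be present and finite.
dinucleotide	dg37_kcal_mol
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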