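# Unit-map template: one entry per line,
#   UNIT chain [first_resno last_resno] [peptide]
# UNIT is VA, VB or PMHC; residue ranges use author numbering and may be
# omitted to take the whole chain. A PMHC unit lists the class-I
# alpha1/alpha2 platform chain (typically residues 1-180 of the MHC heavy
# chain) and the peptide chain, tagged with the word `peptide`.
#
# Entry below matches the synthetic mini-ternary fixture written by
# make-fixtures.R; for crystal structures substitute the chain ids and
# variable-domain residue ranges of the entry at hand.
VA A
VB B
PMHC M
PMHC N
PMHC P peptide
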