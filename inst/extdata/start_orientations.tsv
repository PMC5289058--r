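# Default Vbeta starting rotations (degrees), one per line, expressed as
# components along the Vbeta cuboid axes (1 = long axis). Applied about the
# CoR_beta center. The identity start comes first by convention. The set
# spans the torsion-dominant angular variation of the variable-domain
# packing: +-8 and +-16 about the long axis, +-8 about each minor axis, and
# two combined 8/8 twists; 11 starts in total. Fully overridable from the
# pipeline configuration.
0	0	0
8	0	0
-8	0	0
16	0	0
-16	0	0
0	8	0
0	-8	0
0	0	8
0	0	-8
8	8	0
-8	-8	0
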