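# Ideal (mean) backbone bond lengths and angles for protein structure
# idealization, following the standard Engh & Huber stereochemical
# tabulation used throughout macromolecular refinement.
# kind: bond (Angstrom) or angle (degrees)
# restype: "*" applies to all residue types unless a specific override exists.
kind	name	restype	value
bond	N-CA	*	1.458
bond	N-CA	GLY	1.451
bond	N-CA	PRO	1.466
bond	CA-C	*	1.525
bond	CA-C	GLY	1.516
bond	C-N	*	1.329
bond	C-N	PRO	1.341
bond	C-O	*	1.231
bond	CA-CB	*	1.530
bond	CA-CB	ALA	1.521
bond	N-H	*	1.000
angle	N-CA-C	*	111.2
angle	N-CA-C	GLY	112.5
angle	N-CA-C	PRO	111.8
angle	CA-C-N	*	116.2
angle	CA-C-N	GLY	116.4
angle	C-N-CA	*	121.7
angle	C-N-CA	GLY	120.6
angle	C-N-CA	PRO	122.6
angle	CA-C-O	*	120.8
angle	O-C-N	*	123.0
angle	C-N-H	*	119.2
angle	CA-N-H	*	118.2
angle	N-CA-CB	*	110.5
angle	C-CA-CB	*	110.1
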