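# Coarse backbone-independent rotamer table packaged so the artifact
# builds and tests with no external download.  Means follow the common
# gauche-/gauche+/trans side-chain conventions; probabilities are typical
# relative frequencies; sigmas are generic spreads in degrees.  Unused chi
# columns hold NA.  Users wanting backbone dependence should supply a
# Dunbrack-format library to read_rotamer_library().
aa	prob	m1	m2	m3	m4	s1	s2	s3	s4
SER	0.45	-65	NA	NA	NA	11	NA	NA	NA
SER	0.33	62	NA	NA	NA	11	NA	NA	NA
SER	0.22	180	NA	NA	NA	11	NA	NA	NA
CYS	0.55	-65	NA	NA	NA	11	NA	NA	NA
CYS	0.26	-178	NA	NA	NA	11	NA	NA	NA
CYS	0.19	63	NA	NA	NA	11	NA	NA	NA
THR	0.49	62	NA	NA	NA	10	NA	NA	NA
THR	0.44	-60	NA	NA	NA	10	NA	NA	NA
THR	0.07	-175	NA	NA	NA	10	NA	NA	NA
VAL	0.73	175	NA	NA	NA	10	NA	NA	NA
VAL	0.20	-60	NA	NA	NA	10	NA	NA	NA
VAL	0.07	64	NA	NA	NA	10	NA	NA	NA
ILE	0.60	-65	170	NA	NA	10	11	NA	NA
ILE	0.15	-65	-65	NA	NA	10	11	NA	NA
ILE	0.13	62	170	NA	NA	10	11	NA	NA
ILE	0.12	-57	100	NA	NA	10	11	NA	NA
LEU	0.59	-65	175	NA	NA	10	11	NA	NA
LEU	0.31	-177	65	NA	NA	10	11	NA	NA
LEU	0.10	-85	65	NA	NA	10	11	NA	NA
ASP	0.51	-70	-15	NA	NA	10	14	NA	NA
ASP	0.30	-177	3	NA	NA	10	14	NA	NA
ASP	0.19	63	2	NA	NA	10	14	NA	NA
ASN	0.45	-65	-20	NA	NA	10	16	NA	NA
ASN	0.32	-177	30	NA	NA	10	16	NA	NA
ASN	0.23	62	-10	NA	NA	10	16	NA	NA
HIS	0.45	-65	-70	NA	NA	10	15	NA	NA
HIS	0.33	-177	65	NA	NA	10	15	NA	NA
HIS	0.22	62	-75	NA	NA	10	15	NA	NA
PHE	0.50	-65	85	NA	NA	10	14	NA	NA
PHE	0.35	-177	80	NA	NA	10	14	NA	NA
PHE	0.15	62	90	NA	NA	10	14	NA	NA
TYR	0.50	-65	85	NA	NA	10	14	NA	NA
TYR	0.35	-177	80	NA	NA	10	14	NA	NA
TYR	0.15	62	90	NA	NA	10	14	NA	NA
TRP	0.40	-65	95	NA	NA	10	15	NA	NA
TRP	0.35	-177	-105	NA	NA	10	15	NA	NA
TRP	0.25	62	-90	NA	NA	10	15	NA	NA
PRO	0.55	-27	36	NA	NA	7	7	NA	NA
PRO	0.45	27	-34	NA	NA	7	7	NA	NA
MET	0.40	-65	-65	-70	NA	10	11	13	NA
MET	0.30	-65	175	75	NA	10	11	13	NA
MET	0.30	-177	175	175	NA	10	11	13	NA
GLU	0.40	-65	-65	-40	NA	10	11	15	NA
GLU	0.35	-65	175	-5	NA	10	11	15	NA
GLU	0.25	-177	175	0	NA	10	11	15	NA
GLN	0.40	-65	-65	-40	NA	10	11	16	NA
GLN	0.35	-65	175	0	NA	10	11	16	NA
GLN	0.25	-177	175	20	NA	10	11	16	NA
LYS	0.40	-65	175	175	175	10	11	12	13
LYS	0.30	-177	175	175	175	10	11	12	13
LYS	0.30	-65	-65	175	175	10	11	12	13
ARG	0.35	-65	175	180	180	10	11	13	14
ARG	0.35	-177	175	180	180	10	11	13	14
ARG	0.30	-65	-65	180	180	10	11	13	14
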