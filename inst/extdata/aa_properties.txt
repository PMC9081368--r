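# Amino-acid property tables used by the descriptor encoders.
# Tab-separated key-value records; lines starting with '#' are comments.
#
#   ctd   <property> <class 1|2|3> <residues>   three-class partitions for the
#                                               composition/transition/distribution block
#   group <name>     <residues>                 five side-chain groups (CKSAAGP)
#   triad <class>    <residues>                 seven conjoint-triad classes (KSCTriad)
#   scale <h1|h2|m>  <residue> <value>          Chou's hydrophobicity (h1),
#                                               hydrophilicity (h2) and side-chain
#                                               mass (m); standardized to mean 0 /
#                                               unit variance over the 20 residues
#                                               at load time.
#
# Each ctd/triad partition and the group set covers the 20 standard residues
# exactly once. CTD partitions follow the standard three-class assignments of
# the CTD descriptor literature (class 1/2/3 order is part of the feature
# naming contract and must not be permuted).
ctd	hydrophobicity	1	RKEDQN
ctd	hydrophobicity	2	GASTPHY
ctd	hydrophobicity	3	CLVIMFW
ctd	normwaalsvolume	1	GASTPDC
ctd	normwaalsvolume	2	NVEQIL
ctd	normwaalsvolume	3	MHKFRYW
ctd	polarity	1	LIFWCMVY
ctd	polarity	2	PATGS
ctd	polarity	3	HQRKNED
ctd	polarizability	1	GASDT
ctd	polarizability	2	CPNVEQIL
ctd	polarizability	3	KMHFRYW
ctd	charge	1	KR
ctd	charge	2	ANCQGHILMFPSTWYV
ctd	charge	3	DE
ctd	surfacetension	1	GQDNAHR
ctd	surfacetension	2	KTSEC
ctd	surfacetension	3	ILMFPWYV
ctd	secondarystruct	1	EALMQKRH
ctd	secondarystruct	2	VIYCWFT
ctd	secondarystruct	3	GNPSD
ctd	solventaccess	1	ALFCGIVW
ctd	solventaccess	2	RKQEND
ctd	solventaccess	3	MSPTHY
group	aliphatic	GAVLMI
group	aromatic	FYW
group	positive	KRH
group	negative	DE
group	uncharged	STCPNQ
triad	1	AGV
triad	2	ILFP
triad	3	YMTS
triad	4	HNQW
triad	5	RK
triad	6	DE
triad	7	C
scale	h1	A	0.62
scale	h1	C	0.29
scale	h1	D	-0.90
scale	h1	E	-0.74
scale	h1	F	1.19
scale	h1	G	0.48
scale	h1	H	-0.40
scale	h1	I	1.38
scale	h1	K	-1.50
scale	h1	L	1.06
scale	h1	M	0.64
scale	h1	N	-0.78
scale	h1	P	0.12
scale	h1	Q	-0.85
scale	h1	R	-2.53
scale	h1	S	-0.18
scale	h1	T	-0.05
scale	h1	V	1.08
scale	h1	W	0.81
scale	h1	Y	0.26
scale	h2	A	-0.5
scale	h2	C	-1.0
scale	h2	D	3.0
scale	h2	E	3.0
scale	h2	F	-2.5
scale	h2	G	0.0
scale	h2	H	-0.5
scale	h2	I	-1.8
scale	h2	K	3.0
scale	h2	L	-1.8
scale	h2	M	-1.3
scale	h2	N	0.2
scale	h2	P	0.0
scale	h2	Q	0.2
scale	h2	R	3.0
scale	h2	S	0.3
scale	h2	T	-0.4
scale	h2	V	-1.5
scale	h2	W	-3.4
scale	h2	Y	-2.3
scale	m	A	15.0
scale	m	C	47.0
scale	m	D	59.0
scale	m	E	73.0
scale	m	F	91.0
scale	m	G	1.0
scale	m	H	82.0
scale	m	I	57.0
scale	m	K	73.0
scale	m	L	57.0
scale	m	M	75.0
scale	m	N	58.0
scale	m	P	42.0
scale	m	Q	72.0
scale	m	R	101.0
scale	m	S	31.0
scale	m	T	45.0
scale	m	V	43.0
scale	m	W	130.0
scale	m	Y	107.0
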