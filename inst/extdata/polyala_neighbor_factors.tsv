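# Side-chain neighbor-effect factors for backbone amide hydrogen exchange,
# poly-DL-alanine reference scale, transcribed by hand from the correction
# scheme of Bai, Milne, Mayne & Englander (1993) Proteins 17:75-86 (Table 2),
# as distributed with the Englander laboratory's spreadsheets. Version 1.
#
# All factors are log10 multipliers. For the amide of residue i:
#   log10 k = log10 k_ref(channel, pD)  +  <left column of residue i>
#                                       +  <right column of residue i-1>
# i.e. the "left" column is the effect of a side chain on its own amide
# (the peptide bond on its N-terminal side), the "right" column its effect
# on the amide of the following residue. NT is the N-terminal ammonium group
# (applies its "right" factors to the amide of residue 2); CT is the
# C-terminal carboxylate (applies its "left" factors to the amide of the
# final residue).
#
# Titrating side chains (Asp, Glu, His) carry two rows: form "acid" is the
# protonated species, form "base" the deprotonated one; pKD is the acid
# dissociation constant on the pD scale used to select the applicable form
# (deprotonated above pKD, protonated below).
#
# Reference poly-DL-alanine rate constants at 293 K in D2O (log10 units,
# rates per minute, concentrations molar):
#   log10 kA = 1.62  (acid channel,  k_acid  = 10^(1.62 + AL + AR - pD))
#   log10 kB = 10.05 (base channel,  k_base  = 10^(10.05 + BL + BR + pD - pKD2O))
#   log10 kW = -1.5  (water channel, k_water = 10^(-1.5  + BL + BR))
#   pKD2O = 15.05 (ion product of D2O at 293 K, pD scale)
res	form	pKD	acid_left	acid_right	base_left	base_right
A	-	NA	0.00	0.00	0.00	0.00
R	-	NA	-0.59	-0.32	0.08	0.22
N	-	NA	-0.58	-0.13	0.49	0.32
D	acid	4.48	-0.90	-0.12	0.69	0.60
D	base	4.48	0.90	0.58	0.10	-0.18
C	-	NA	-0.54	-0.46	0.62	0.55
G	-	NA	-0.22	0.22	0.27	0.17
Q	-	NA	-0.47	-0.27	0.06	0.20
E	acid	4.93	-0.60	-0.27	0.24	0.39
E	base	4.93	-0.90	0.31	-0.51	-0.15
H	acid	7.42	-0.80	-0.51	0.80	0.83
H	base	7.42	0.00	0.00	-0.10	0.14
I	-	NA	-0.91	-0.59	-0.73	-0.23
L	-	NA	-0.57	-0.13	-0.58	-0.21
K	-	NA	-0.56	-0.29	-0.04	0.12
M	-	NA	-0.64	-0.28	-0.01	0.11
F	-	NA	-0.52	-0.43	-0.24	0.06
P	-	NA	NA	-0.19	NA	-0.24
S	-	NA	-0.44	-0.39	0.37	0.30
T	-	NA	-0.79	-0.47	-0.07	0.20
W	-	NA	-0.40	-0.44	-0.41	-0.11
Y	-	NA	-0.41	-0.37	-0.27	0.05
V	-	NA	-0.74	-0.30	-0.70	-0.14
NT	-	NA	NA	-1.32	NA	1.62
CT	-	NA	0.96	NA	-1.80	NA
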