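Species	Group	PKS;NRPS	NPS11/ETP mod 1	NPS12/ETP mod 2	NPS10	CYCLO	SID	ACV	AAR	EAS	Other	Total
A. fumigatus	Euascomycota	1	2^c^	1	1	1	1	0	1	10	2	20
A. nidulans	Euascomycota	1	0	1	1	2^d^	1	1	1	11	0	19
B. cinerea	Euascomycota	3^e^	1	0	0	0	3	0	1	5	1	14
C. immitis	Euascomycota	1	0	0	0	0	1	0	1	5	0	8
C. heterostrophus	Euascomycota	0	1	2	1	2^d^	1	0	1	6	1	15
F. graminearum	Euascomycota	1	0	3	1	1	2	0	1	12	0	21
M. oryzae	Euascomycota	6	1	1	1	1^d^	1	0	1	4	2	18
N. crassa	Euascomycota	0	0	0	0	0	1	0	1	2	0	4
P. anserina	Euascomycota	4	0	1	0	0	1	0	1	4	1	12
T. reesii	Euascomycota	2	2^c^	1	1	0	1	0	1	5	0	13
C. cinerea	Basidiomycota	0	0	3	0	0	1	0	1	0	0	5
C. neoformans	Basidiomycota	0	0	0	0	0	0	0	1	0	0	1
L. bicolor	Basidiomycota	0	0	0	0	0	0	0	1	0	0	1
P. chrysosporium	Basidiomycota	0	0	1	0	1	0	0	1	0	0	3
P. stipitis	Basidiomycota	0	0	0	0	0	0	0	1	0	0	1
P. placenta	Basidiomycota	0	0	8	0	0	0	0	2	0	0	10
P. graminis	Basidiomycota	0	0	0	0	0	0	0	1	0	1	2
S. roseus	Basidiomycota	0	0	0	0	0	0	0	1	0	1	2
U. maydis	Basidiomycota	0	0	0	1	0	2	0	1	0	1	5
S. japonicus	Schizosaccharomycota	0	0	0	0	0	1	0	1	0	0	2
S. pombe	Schizosaccharomycota	0	0	0	0	0	1	0	1	0	0	2
Hemiascomycota_all	Hemiascomycota	0	0	0	0	0	0	0	1	0	0	1
P. blakesleeanus	Zygomycota	0	0	0	0	0	0	0	1	0	0	1
R. oryzae	Zygomycota	0	0	0	0	0	0	0	1	0	0	1
B. dendrobatidis	Chytridiomycota	0	0	2	0	0	0	0	1	0	0	3
E. cuniculi	Microsporidia	0	0	0	0	0	0	0	0	0	0	0
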