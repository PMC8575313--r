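human_gene	fly_gene	diopt_score	has_rnai_line
ACO2	Acon	12	TRUE
ACSM1	pdgy	1	TRUE
ACSM3	pdgy	1	TRUE
AGAP6	CenG1A	8	TRUE
ALK	Alk	12	TRUE
BMP2K	Nak	7	TRUE
CAPN8	CalpA	10	TRUE
CDS1	CdsA	13	TRUE
CHIT1	Cht7	10	TRUE
CPA4	CG3097	9	TRUE
DCHS1	ds	13	TRUE
DNAH10	Dhc98D	13	TRUE
ITPKB	IP3K2	10	TRUE
ITPR1	Itp-r83A	15	TRUE
LPIN1	Lpin	13	TRUE
MYH15	Mhc	12	TRUE
NUP133	Nup133	13	TRUE
OVGP1	Cht7	7	TRUE
PAPSS1	Papss	14	TRUE
PGBD4	CG9839	7	TRUE
PLEKHG1	GEFmeso	8	TRUE
SCO1	Scox	14	TRUE
SDK1	sdk	8	TRUE
SYNE1	Msp300	5	TRUE
SYNE2	Msp300	4	TRUE
TJP3	pyd	7	TRUE
TTN	bt	9	TRUE
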