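gene	probe_id	p_value	category	lower_in_above_median
MAGOHB	218894_s_at	7.39E-05	rna_processing	FALSE
PAPOLA	212720_at	8.98E-06	rna_processing	FALSE
PNPT1	225291_at	5.46E-10	rna_processing	FALSE
POP4	202868_s_at	1.99E-03	rna_processing	FALSE
PPIH	204228_at	1.77E-05	rna_processing	FALSE
RBM39	208720_s_at	9.41E-05	rna_processing	FALSE
RPS6	209134_s_at	4.64E-03	rna_processing	TRUE
SUPT16H	233827_s_at	7.69E-05	rna_processing	FALSE
TXNL4A	202836_s_at	5.81E-07	rna_processing	FALSE
EIF2S1	201144_s_at	1.75E-07	stress_response	FALSE
GNA13	224761_at	7.16E-09	stress_response	FALSE
GNB1	200744_s_at	8.14E-05	stress_response	FALSE
HLA-DRA	208894_at	2.33E-05	stress_response	FALSE
PRDX2	215067_x_at	3.39E-04	stress_response	TRUE
PRDX3	209766_at	4.39E-03	stress_response	TRUE
RAD23A	201039_s_at	2.33E-04	stress_response	FALSE
RPS6	209134_s_at	4.64E-03	stress_response	TRUE
RUNX1	210365_at	4.85E-06	stress_response	TRUE
SMC6	218781_at	2.95E-05	stress_response	FALSE
SUPT16H	233827_s_at	7.69E-05	stress_response	FALSE
ABCB10	223320_s_at	3.50E-03	other	FALSE
ABCF1	200045_at	1.04E-09	other	FALSE
BAT5	224756_s_at	2.01E-06	other	FALSE
BMP2K	37170_at	6.77E-03	other	TRUE
C17orf95	225808_at	5.28E-08	other	FALSE
C19orf56	217780_at	1.64E-03	other	FALSE
C5orf22	203738_at	5.40E-03	other	FALSE
CAP1	213798_s_at	7.70E-06	other	FALSE
CBX7	212914_at	2.68E-04	other	TRUE
CHCHD3	217972_at	5.68E-07	other	FALSE
CHCHD4	229595_at	1.90E-05	other	FALSE
CLASP2	212308_at	8.48E-03	other	TRUE
CLDND1	208925_at	1.06E-04	other	FALSE
DDX19A	202578_s_at	1.52E-05	other	FALSE
DNAJC10	221781_s_at	9.41E-12	other	FALSE
GADD45GIP1	212891_s_at	2.13E-03	other	FALSE
GBP1	202270_at	1.17E-05	other	FALSE
HLA-B	208729_x_at	9.92E-06	other	FALSE
KIF5B	224662_at	2.39E-05	other	FALSE
MCART1	232092_at	1.86E-06	other	FALSE
MCM6	201930_at	1.79E-07	other	FALSE
MTFR1	203207_s_at	1.79E-07	other	FALSE
NRD1	208709_s_at	4.64E-08	other	FALSE
PDK1	206686_at	5.81E-06	other	FALSE
PDXDC1	212053_at	1.30E-05	other	FALSE
PEBP1	211941_s_at	9.61E-05	other	FALSE
PHF20	235389_at	1.62E-03	other	FALSE
PI4K2B	222631_at	1.87E-11	other	FALSE
PIGO	209998_at	5.92E-03	other	FALSE
PPME1	217841_s_at	2.47E-04	other	FALSE
RAB6B	221792_at	1.08E-04	other	TRUE
SAPS3	222467_s_at	3.76E-06	other	FALSE
SCAND1	231059_x_at	3.21E-08	other	FALSE
SHC1	201469_s_at	2.47E-03	other	FALSE
SLC15A2	240159_at	6.86E-03	other	TRUE
SNX6	222410_s_at	5.35E-12	other	FALSE
TM2D2	224413_s_at	3.83E-08	other	FALSE
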