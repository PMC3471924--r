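gene	probe_id	p_value	category	lower_in_above_median
CAD	202715_at	2.63E-03	mitosis	FALSE
CCNK	225824_at	2.07E-03	mitosis	FALSE
CDC7	204510_at	4.27E-06	mitosis	FALSE
CDT1	228868_x_at	1.21E-08	mitosis	FALSE
CENPH	231772_x_at	1.45E-04	mitosis	FALSE
CHEK1	205393_s_at	6.03E-09	mitosis	FALSE
EZH2	203358_s_at	8.18E-12	mitosis	FALSE
GINS1	206102_at	2.95E-07	mitosis	FALSE
HELLS	220085_at	3.39E-04	mitosis	FALSE
MCM2	202107_s_at	8.02E-07	mitosis	FALSE
MCM3	201555_at	6.17E-05	mitosis	FALSE
MCM4	212141_at	5.50E-07	mitosis	FALSE
MCM5	201755_at	4.47E-09	mitosis	FALSE
MCM6	201930_at	9.09E-13	mitosis	FALSE
MCM7	208795_s_at	2.14E-05	mitosis	FALSE
MYC	202431_s_at	2.92E-03	mitosis	FALSE
POLD1	203422_at	1.51E-04	mitosis	FALSE
PRIM1	205053_at	9.19E-03	mitosis	FALSE
RFC5	203209_at	5.46E-04	mitosis	FALSE
RRM2	201890_at	1.74E-13	mitosis	FALSE
SNRPD3	202567_at	1.18E-06	mitosis	FALSE
TK1	202338_at	1.14E-11	mitosis	FALSE
TYMS	202589_at	3.61E-09	mitosis	FALSE
UHRF1	225655_at	3.07E-10	mitosis	FALSE
WDHD1	216228_s_at	2.34E-06	mitosis	FALSE
CCDC86	203119_at	1.05E-05	other	FALSE
ELOVL6	204256_at	8.42E-04	other	FALSE
GABRP	205044_at	5.67E-06	other	FALSE
KRT17	205157_s_at	5.87E-03	other	FALSE
MMP12	204580_at	2.68E-05	other	FALSE
NUP107	218768_at	5.26E-04	other	FALSE
NUTF2	202397_at	1.34E-04	other	FALSE
PA2G4	208676_s_at	3.67E-03	other	FALSE
SLC7A5	201195_s_at	5.40E-14	other	FALSE
SQLE	209218_at	1.45E-06	other	FALSE
WASF1	204165_at	6.87E-03	other	FALSE
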