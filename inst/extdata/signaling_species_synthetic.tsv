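id	initial_concentration	is_boundary	tags
EGF	5e-04	0	
EGFR	0.5	0	
EGFR_EGF	0	0	
EGFR2	0	0	
EGFR2_p	0	0	
Shc	0.5	0	
EGFR2_p_Shc	0	0	
EGFR2_p_pShc	0	0	
Grb2	0.5	0	
EGFR2_p_pShc_Grb2	0	0	
SOS	0.25	0	
EGFR2_p_pShc_Grb2_SOS	0	0	
pShc	0	0	
EGFR2_p_Grb2	0	0	
EGFR2_p_Grb2_SOS	0	0	
Grb2_SOS	0	0	
EGFR2_i	0	0	
RasGDP	0.5	0	
RasGTP	0	0	
pShc_Grb2_SOS	0	0	
GAP	0.1	0	
Raf	0.5	0	
Raf_RasGTP	0	0	
Raf_act	0	0	observable:Raf1_active
PP5	0.2	0	
PP5_Raf_act	0	0	observable:Raf1_active
MEK	0.7	0	
Raf_act_MEK	0	0	observable:Raf1_active
MEK_p	0	0	
Raf_act_MEKp	0	0	observable:Raf1_active
MEK_pp	0	0	observable:ppMEK
ERK	1	0	
MEKpp_ERK	0	0	observable:ppMEK
ERK_p	0	0	
MEKpp_ERKp	0	0	observable:ppMEK
ERK_pp	0	0	observable:ppERK
PP2A	0.3	0	
PP2A_MEKpp	0	0	observable:ppMEK
PP2A_MEKp	0	0	
MKP	0.3	0	
MKP_ERKpp	0	0	observable:ppERK
MKP_ERKp	0	0	
ERK_pp_n	0	0	observable:ppERK
SOS_i	0	0	
PI3K	0.3	0	
EGFR2_p_PI3K	0	0	observable:PI3K_active
PIP2	10	0	
PIP3	0	0	
Gbg	0	0	
Gbg_PI3K	0	0	observable:PI3K_active
PTEN	0.3	0	
Akt	0.5	0	
Aktm	0	0	
PDK1	0.2	0	
PDK1_PIP3	0	0	
Akt_p	0	0	
JAK	0.3	0	
EGFR2_p_JAK	0	0	
JAK_act	0	0	
STAT	0.5	0	
EGFR2_p_STAT	0	0	
STAT_p	0	0	
STAT_dim	0	0	
STAT_dim_n	0	0	
Tam	0	0	
GPR30	0.3	0	
GPR30_Tam	0	0	
G_trimer	0.5	0	
GPR30_Tam_G	0	0	
Ga_GTP	0	0	
Ga_GDP	0	0	
AC	0.2	0	
AC_act	0	0	
cAMP	0	0	
PDE	0.2	0	
AMP	0	0	
PKA	0.3	0	
PKA_act	0	0	
PLC	0.3	0	
PLC_act	0	0	
IP3	0	0	
DAG	0	0	
PKC	0.5	0	
PKC_DAG	0	0	
PKC_act	0	0	
Src	0.5	0	
Src_act	0	0	
proMMP	0.5	0	
MMP	0	0	
MMP_i	0	0	
HBEGF_m	1	1	
GRK	0.1	0	
GPR30_Tam_GRK	0	0	
GPR30_Tam_p	0	0	
bArr	0.2	0	
GPR30_Tam_p_bArr	0	0	
GPR30_i_bArr	0	0	
GPR30_i	0	0	
bArr2	0.1	0	
GPR30_Tam_p_bArr2	0	0	
Elk1	0.3	0	
Elk1_p	0	0	
Fos	0	0	
Myc	0	0	
Jun	0	0	
AP1	0	0	
MKP_n	0.05	0	
ERK_p_n	0	0	
p53	0.2	0	
p53_p	0	0	
Mdm2	0.1	0	
p53_Mdm2	0	0	
p53_gene	1	1	
PUMA	0	0	
Bax	0	0	
Bcl2	0.2	0	
Bax_Bcl2	0	0	
HK	1	1	
CytC_m	1	0	
CytC_c	0	0	
Casp9	0.3	0	
Casp9_act	0	0	
Casp3	0.3	0	
Casp3_act	0	0	
ERK_n	0	0	
pShc_Grb2	0	0	
GPR30_G	0	0	
GPR30_Tam_bArr	0	0	
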