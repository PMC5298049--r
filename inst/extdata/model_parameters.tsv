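symbol	value	unit	cell	description
F_i	0.23	uM/s	SMC	maximal IP3R-mediated Ca2+ release flux
Kr_i	1	uM	SMC	half-saturation IP3 concentration for IP3R release
B_i	2.025	uM/s	SMC	maximal SERCA (SR uptake) rate
cb_i	1	uM	SMC	half-saturation cytosolic Ca2+ for SR uptake
C_i	55	uM/s	SMC	maximal CICR rate
sc_i	2	uM	SMC	half-saturation store Ca2+ for CICR
cc_i	0.9	uM	SMC	half-saturation cytosolic Ca2+ for CICR
D_i	0.24	1/s	SMC	rate constant of Ca2+ extrusion by membrane ATPase
vd_i	-100	mV	SMC	intercept of voltage dependence of extrusion
Rd_i	250	mV	SMC	slope of voltage dependence of extrusion
L_i	0.025	1/s	SMC	SR leak rate constant
G_Ca	0.00129	uM/mV/s	SMC	whole-cell conductance of VOCCs
v_Ca1	100	mV	SMC	reversal potential of VOCCs
v_Ca2	-24	mV	SMC	half-activation potential of VOCCs
R_Ca	8.5	mV	SMC	activation slope of VOCCs
G_NaCa	0.00316	uM/mV/s	SMC	whole-cell Na+/Ca2+ exchange conductance
c_NaCa	0.5	uM	SMC	half-saturation Ca2+ for Na+/Ca2+ exchange
v_NaCa	-30	mV	SMC	reversal potential of Na+/Ca2+ exchange
F_NaK	0.0432	uM/s	SMC	net whole-cell Na+/K+-ATPase current (flux form)
G_Cl	0.00134	uM/mV/s	SMC	whole-cell chloride conductance
v_Cl	-25	mV	SMC	reversal potential of chloride channels
G_K	0.00446	uM/mV/s	SMC	whole-cell conductance of Ca2+-activated K+ channels
v_K	-94	mV	SMC	reversal potential of K+ channels
lambda_i	45	1/s	SMC	rate constant of K+ channel activation relaxation
c_w	0	uM	SMC	Ca2+ shift of K+ channel activation
beta_i	0.13	uM^2	SMC	translation factor of K+ channel activation
v_Ca3	-27	mV	SMC	half-activation potential of K+ channel Ca2+ gating
R_K	12	mV	SMC	activation slope of K+ channel voltage gating
gamma_i	1970	mV/uM	SMC	scaling factor converting net ion flux to membrane potential change
k_i	0.1	1/s	SMC	IP3 degradation rate constant
F_j	0.23	uM/s	EC	maximal IP3R-mediated Ca2+ release flux
Kr_j	1	uM	EC	half-saturation IP3 concentration for IP3R release
B_j	0.5	uM/s	EC	maximal ER uptake (SERCA) rate
cb_j	1	uM	EC	half-saturation cytosolic Ca2+ for ER uptake
C_j	5	uM/s	EC	maximal CICR rate
sc_j	2	uM	EC	half-saturation store Ca2+ for CICR
cc_j	0.9	uM	EC	half-saturation cytosolic Ca2+ for CICR
D_j	0.24	1/s	EC	rate constant of Ca2+ extrusion
L_j	0.025	1/s	EC	ER leak rate constant
G_cat	0.00066	uM/mV/s	EC	whole-cell conductance of Ca2+-permeable nonselective cation channels
E_Ca	50	mV	EC	reversal potential of the cation channels
m3_cat	-0.18	log10(uM)	EC	half-activation log Ca2+ of cation channels
m4_cat	0.37	log10(uM)	EC	activation slope of cation channels
J0_j	0.029	uM/s	EC	constant background Ca2+ influx
C_m	25.8	pF	EC	membrane capacitance
G_tot	6927	pS	EC	total conductance of Ca2+-activated K+ channels (BKCa plus SKCa)
v_K_j	-80	mV	EC	reversal potential of EC K+ channels
a1_j	53.3	mV	EC	BKCa activation shift constant
a2_j	53.3	mV/log10(uM)	EC	BKCa Ca2+/voltage interaction slope
b_j	-80.8	mV	EC	BKCa half-activation potential offset
c0_j	-0.4	log10(uM)	EC	BKCa half-activation log Ca2+
m3b_j	0.00132	1/mV^2	EC	BKCa activation curvature constant
m4b_j	0.3	-	EC	BKCa activation width constant
m3s_j	-0.28	log10(uM)	EC	SKCa half-activation log Ca2+
m4s_j	0.389	log10(uM)	EC	SKCa activation slope
G_R	955	pS	EC	residual (leak) whole-cell conductance
v_rest_j	-31.1	mV	EC	reversal potential of the residual current
k_j	0.1	1/s	EC	IP3 degradation rate constant
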