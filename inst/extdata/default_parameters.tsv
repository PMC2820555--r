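name	value	class	source	description
rho	0.11	reaction	calibrated	amplitude of the tip-anchored WUS/facX reaction rate; multiplies the anchoring profile (and its frozen random perturbation) in the WUS production and facX consumption terms; the published table gives this entry only as the anchoring distribution itself
b_w	0.0065	reaction	calibrated	basal offset inside the WUS autocatalytic term, seeds WUS ignition
kappa_w	0.6	kinetic	published	saturation constant of the WUS autocatalytic term W^2/(1+kappa_w*W^2)
k_rep	0.72	kinetic	calibrated	CLV3 action constant in the WUS repression factor 1/(1+(k_rep*Ctot)^n_rep); 1/k_rep is the switching threshold of CLV signalling
n_rep	32	kinetic	calibrated	Hill exponent of CLV3 action on WUS production; the switch-like response reproduces both the robustness to graded endogenous CLV3 and the sharp response to uniform overexpression
nu_f	0.002	basal	published	basal production rate of facX in every cell
K_f	0.5	kinetic	published	half-saturation facX concentration of WUS production (enzyme-limited activation); caps how far facX accumulation can compensate WUS repression
r_y	0.0275	reaction	calibrated	WUS-signal production rate per unit WUS
d_y	0.005	degradation	calibrated	WUS-signal degradation rate
K_y	0.55	kinetic	calibrated	half-maximal WUS-signal concentration of the stemness response
n_hill	8	kinetic	calibrated	Hill exponent of the stemness response (large, for a sharp stem-cell transition)
r_st	0.002	reaction	calibrated	maximal stemness production rate in competent cells; r_st/d_st = 1 fixes the saturated stemness level at the published dimensionless value 1
d_st	0.002	degradation	published	stemness decay rate; slow, so stem-cell identity is a persistent cell state
r_c	0.15	reaction	calibrated	endogenous CLV3 production rate per unit stemness
d_c	0.05	degradation	published	CLV3 degradation rate
d_w	0.004	degradation	published	WUS degradation rate
d_f	0.004	degradation	published	facX degradation rate
D_w	0.0005	diffusion	calibrated	WUS leakage diffusion rate (WUS protein is essentially immobile)
D_f	0.02	diffusion	published	facX free diffusion rate
D_y	0.02	diffusion	published	WUS-signal free diffusion rate
D_st	0.002	diffusion	calibrated	stemness leakage diffusion rate
D_c	0.02	diffusion	published	CLV3 free diffusion rate
xi_amp	0.02	noise	calibrated	half-width of the uniform random perturbation added to the anchoring profile (frozen per cell at initialisation)
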