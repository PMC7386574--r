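# Festuca pratensis (grass), monoculture parameter set.
# Units: h_max cm; f_s g cm^-3; SLA cm^2 g^-1; SRL cm g^-1; N_seed_meta m^-2 d^-1;
# t_meta julian day; t_em d; h_min m; age_rep yr; LLS, RLS d; m_seed d^-1;
# m_basic yr^-1; p_max umol_CO2 m^-2 s^-1; alpha umol_CO2 umol_photons^-1;
# WUE g_ODM kg_H2O^-1; r_m d^-1.
species: F_pratensis
h_max: 120
hw: 1.5
f_s: 0.00072
f_O: 1
SLA: 117.48
SRL: 42462.8
rooting_depth_powerlaw: [3.506, 0.301]
sr: 2.2
N_seed_meta: 4013
t_meta: 136
t_em: 14
germ_pct: 0.3
h_min: 0.03
age_rep: 0.2
LLS: 219
RLS: 166
m_seed: 0.038
m_basic: 0.02
life: perennial
p_max: 17
alpha: 0.07
k: 0.8
m: 0.1
WUE: 2.7
CN_green: 18
CN_sen: 39
N_fix: no
alloc_shoot: 0.50
r_m: 0.02
r_g: 0.2
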