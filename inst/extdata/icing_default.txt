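# Default ICING model parameter set ("icing-default-1").
# Literature-standard reconstruction of the clinically used
# glucose-insulin-nutrition model for critically ill adults; every value can
# be overridden via icing_params().
p_G: 0.006       # 1/min, non-insulin-mediated glucose clearance
alpha_G: 0.0154  # L/mU, saturation of insulin-mediated uptake (1/65)
EGP: 1.16        # mmol/min, endogenous glucose production
CNS: 0.3         # mmol/min, central nervous system glucose uptake
V_G: 13.3        # L, glucose distribution volume
n_I: 0.006       # 1/min, plasma-interstitium insulin diffusion
n_C: 0.006       # 1/min, interstitial insulin degradation
n_K: 0.0542      # 1/min, renal insulin clearance
n_L: 0.1578      # 1/min, hepatic insulin clearance
alpha_I: 0.0017  # L/mU, saturation of hepatic insulin clearance
x_L: 0.67        # -, first-pass hepatic extraction of endogenous insulin
V_I: 4.0         # L, insulin distribution volume
d1: 0.0347       # 1/min, stomach-to-gut glucose transfer rate
d2: 0.0069       # 1/min, gut-to-plasma glucose emptying rate
P_max: 6.11      # mmol/min, saturable ceiling on gut emptying
u_en: 0          # mU/min, constant endogenous insulin secretion
                 # (default 0: suppressed secretion in critical illness)
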