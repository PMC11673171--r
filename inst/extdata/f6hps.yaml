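# Setup 1: F6HPS dialyzer, BSA both sides, Qb 180 / Qd 90 mL/min, 3 h.
# Transport coefficients are the values fitted on this condition
# (KfreeA at 500 mL/min = 2500 mL/min, urea-literature beta).
dialyzer:
  n_fibers: 8400
  r_inner_um: 100.0
  r_outer_um: 140.0
  fiber_length_cm: 21.0
  housing_radius_mm: 20.0
  area_nominal_m2: 1.3
  Lp_m_per_s_Pa: 8.61e-11
  sigma: 0.0
fluids:
  mu_blood_Pa_s: 6.9e-4
  mu_dialysate_Pa_s: 6.9e-4
solute:
  KB_per_M: 5.0e+6
  mw_toxin_g_mol: 584.66
  mw_binder_g_mol: 66430.0
operating:
  Qb_ml_min: 180.0
  Qd_ml_min: 90.0
  Vb_ml: 628.33
  Vd_ml: 626.67
  Cb_toxin0_mg_dl: 15.37
  Cb_albumin_g_dl: 2.24
  Cd_albumin_g_dl: 1.77
  Cd_toxin0_mg_dl: 0.0
  duration_h: 3.0
transport:
  KfreeA_at_500_ml_min: 2500.0
  beta_Qd: 0.05544
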