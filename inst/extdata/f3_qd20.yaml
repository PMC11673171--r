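# Setup 3 (test): F3 dialyzer, Qb 150, Qd 20 mL/min, 5 h.
# Conductance rescaled from the F6HPS fit by nominal area (0.4/1.3);
# beta is the best-fit flow-dependence for this membrane.
dialyzer:
  n_fibers: 2304
  r_inner_um: 100.0
  r_outer_um: 140.0
  fiber_length_cm: 20.0
  housing_radius_mm: 11.0
  area_nominal_m2: 0.4
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
  Qb_ml_min: 150.0
  Qd_ml_min: 20.0
  Vb_ml: 200.0
  Vd_ml: 200.0
  Cb_toxin0_mg_dl: 16.76
  Cb_albumin_g_dl: 2.13
  Cd_albumin_g_dl: 2.29
  Cd_toxin0_mg_dl: 0.0
  duration_h: 5.0
transport:
  KfreeA_at_500_ml_min: 769.23
  beta_Qd: 0.45
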