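# Default kinetic/transport parameters (uM, um, s).
# Provenance and descriptions: parameterTable() in the package.
values:
  D_auxin: 220.0
  D_auxin_wall: 110.0
  D_ET: 600.0
  D_CK: 60.0
  D_PLSp: 10.0
  D_PINp: 10.0
  D_AUX1p: 10.0
  P_PIN: 2.5
  P_AUX1: 1.5
  sigma_PIN_ref: 8.0
  sigma_PIN_max: 24.0
  sigma_AUX1_ref: 1.2
  sigma_AUX1_max: 3.6
  I0_auxin: 2.8
  K_X_influx: 0.12
  k_bnd_ET: 5.0
  k_bnd_CK: 1.0
  ET_shoot: 1.5
  CK_shoot: 0.1
  k_auxin_basal: 2.0e-05
  k_auxin_X: 0.0002
  K_auxin_X: 0.3
  K_auxin_CK: 0.25
  r_auxin_CK: 0.1
  d_auxin: 0.001
  k_CK_syn: 0.04
  K_CK_auxin: 0.03
  d_CK: 0.006
  k_ET_basal: 0.002
  k_ET_syn: 0.01
  K_ET_auxin: 0.005
  K_ET_CK: 0.005
  d_ET: 0.01
  Ra_total: 1.0
  k_Ra_on: 1.0
  k_Ra_off: 6.0
  Re_total: 1.0
  k_Re_act: 0.02
  k_Re_PLS: 0.6
  k_ET_bind: 1.0
  CTR_total: 1.0
  k_CTR_act: 0.3
  k_CTR_deact: 0.3
  k_X_syn: 0.09
  K_X_CTR: 0.05
  d_X: 0.06
  k_PLSm_basal: 2.0e-05
  k_PLSm_auxin: 0.004
  K_PLSm_Ra: 0.15
  K_PLSm_X: 0.3
  d_PLSm: 0.01
  k_PLSp_tln: 0.1
  d_PLSp: 0.01
  k_PLSm_ox: 0.0
  pls_ablation_act: 0.5
  k_PINm_basal: 0.0014
  a_PINm_auxin: 0.8
  K_PINm_auxin: 0.3
  a_PINm_X: 12.0
  K_PINm_X: 1.0
  K_PINm_CK: 3.0
  d_PINm: 0.01
  k_PINp_tln: 0.05
  d_PINp: 0.006
  k_PIN_exo: 0.2
  k_PIN_endo: 0.06
  K_PIN_endo_auxin: 0.5
  k_AUX1m_basal: 0.0002
  k_AUX1m_X: 0.002
  K_AUX1m_X: 0.2
  d_AUX1m: 0.01
  k_AUX1p_tln: 0.05
  d_AUX1p: 0.006
  k_AUX1_exo: 0.2
  k_AUX1_endo: 0.06
  init_conc: 0.1
flags:
  ck_activates_auxin: no
  pls_auxin_regulation_off: no
  strict_flux: no
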