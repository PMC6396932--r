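# Calibrated default parameter set, 5-state hierarchy
# (LT-HSC -> ST-HSC -> MPP -> CMP -> Terminal).
# Proliferation and secretion are constant in this variant.
kind: five_state
init:
  LT_HSC: 500.0
  ST_HSC: 3000.0
  MPP: 1500.0
  CMP: 0.0
  Terminal: 0.0
params:
  PR_LT_HSC: 0.9
  PR_ST_HSC: 0.9
  PR_MPP: 0.7
  PR_CMP: 0.9
  PR_Terminal: 0.64
  death_max_LT_HSC: 0.55
  death_max_ST_HSC: 0.3
  death_max_MPP: 0.3
  death_max_CMP: 0.35
  death_max_Terminal: 0.3
  d_LT_HSC: 0.05
  d_ST_HSC: 1.0
  d_MPP: 1.0
  d_CMP: 1.0
  d_Terminal: 1.0
  f_max_LT_HSC: 0.9
  s_LT_HSC: 0.001
  f_max_ST_HSC: 0.85
  s_ST_HSC: 0.001
  f_max_MPP: 0.65
  s_MPP: 0.001
  f_max_CMP: 0.6
  s_CMP: 0.001
  q_max_LT_HSC: 0.9
  q_max_ST_HSC: 0.3
  q_max_MPP: 0.3
  j_max_ST_HSCtoTerminal: 0.55
  j_max_MPPtoTerminal: 0.5
  DR_LTtoST: 0.55
  DR_STtoMPP: 0.7
  DR_MPPtoCMP: 0.7
  DR_CMPtoTerminal: 3.0
  DR_STtoTerminal: 2.0
  DR_MPPtoTerminal: 3.5
  c_Prog_DiffS: 1.0e-4
  c_Prog_DiffI: 2.0e-6
  c_Prog_ProS: 1.0e-5
  c_Prog_ProI: 2.0e-6
  c_Term_DiffS: 3.0e-6
  c_Term_DiffI: 1.0e-5
  c_Term_ProS: 1.0e-6
  c_Term_ProI: 1.0e-6
  K_SCF_consumption: 2.0e-4
  K_GC_consumption: 2.0e-6
  t_hat: 1.0
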