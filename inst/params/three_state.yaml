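# Calibrated default parameter set, 3-state hierarchy (LSK -> CMP -> Terminal).
# Units: rates 1/day; secretion ng/cell/day; s_* mL/ng; d_* 1/mM;
# K_SCF_consumption ng/cell/day; K_GC_consumption mM/cell/day;
# c_hat ng/mL, s_hat ng/mL, t_hat dimensionless reference scales.
kind: three_state
init:
  LSK: 5000.0
  CMP: 0.0
  Terminal: 0.0
params:
  PR_max_LSK: 1.1
  PR_max_CMP: 1.0
  PR_max_Terminal: 0.61
  death_max_LSK: 0.3
  death_max_CMP: 0.35
  death_max_Terminal: 0.3
  d_LSK: 1.0
  d_CMP: 1.0
  d_Terminal: 1.0
  f_max_LSK: 0.85
  s_LSK: 0.001
  f_max_CMP: 0.6
  s_CMP: 0.001
  q_max_LSK: 0.3
  j_max_LSK: 0.5
  DR_LSKtoCMP: 0.5
  DR_LSKtoTerminal: 2.2
  DR_CMPtoTerminal: 3.0
  m_Prog_DiffS: 2.0e-4
  m_Prog_DiffI: 2.0e-6
  m_Prog_ProS: 1.0e-5
  m_Prog_ProI: 2.0e-6
  m_Term_DiffS: 1.0e-6
  m_Term_DiffI: 1.0e-5
  m_Term_ProS: 1.0e-6
  m_Term_ProI: 1.0e-6
  K_SCF_consumption: 5.0e-5
  K_GC_consumption: 2.0e-6
  c_hat: 5.0
  s_hat: 1.0
  t_hat: 1.0
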