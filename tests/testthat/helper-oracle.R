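# Independent, deliberately naive re-implementation of the model's rate laws
# and flow wiring, used only as a cross-check oracle for the package RHS.
# Everything is written scalar-by-scalar, straight from the rate-law
# definitions, sharing no code with the package internals.

oracle_ratio <- function(num, den) {
  if (num == 0) return(0)
  num / max(den, 1e-9)
}

oracle_rhs_three <- function(pop, env, p, vol_uL = 300) {
  vol <- vol_uL / 1000
  lsk <- pop[["LSK"]]; cmp <- pop[["CMP"]]; term <- pop[["Terminal"]]
  scf <- env[["scf_conc"]]; gc <- env[["gc_conc"]]
  ds <- env[["pool_DiffS"]]; di <- env[["pool_DiffI"]]
  ps <- env[["pool_ProS"]]; pi_ <- env[["pool_ProI"]]

  rd <- oracle_ratio(ds, di)
  rp <- oracle_ratio(ps, pi_)
  f_l <- p[["f_max_LSK"]] / (1 + rd + p[["s_LSK"]] * scf)
  f_c <- p[["f_max_CMP"]] / (1 + rd + p[["s_CMP"]] * scf)
  q <- p[["q_max_LSK"]] * exp(-rd)
  td <- p[["m_Term_DiffS"]] * term
  j <- p[["j_max_LSK"]] * exp(-td / p[["t_hat"]])
  pr <- function(prmax) prmax * (1 - exp(-scf * rp / p[["s_hat"]]))
  dth <- function(dmax, d) dmax / (1 + d * gc)

  grow_l <- (1 - q) * f_l * pr(p[["PR_max_LSK"]]) * lsk
  to_cmp <- (1 - q) * (1 - f_l) * (1 - j) * p[["DR_LSKtoCMP"]] * lsk
  to_term_jump <- (1 - q) * (1 - f_l) * j * p[["DR_LSKtoTerminal"]] * lsk
  grow_c <- f_c * pr(p[["PR_max_CMP"]]) * cmp
  cmp_out <- (1 - f_c) * p[["DR_CMPtoTerminal"]] * cmp

  d_lsk <- grow_l - to_cmp - to_term_jump -
    dth(p[["death_max_LSK"]], p[["d_LSK"]]) * lsk
  d_cmp <- to_cmp + grow_c - cmp_out -
    dth(p[["death_max_CMP"]], p[["d_CMP"]]) * cmp
  d_term <- to_term_jump + cmp_out + pr(p[["PR_max_Terminal"]]) * term -
    dth(p[["death_max_Terminal"]], p[["d_Terminal"]]) * term

  n <- lsk + cmp + term
  pools_in <- c(ds, di, ps, pi_)
  m_prog <- c(p[["m_Prog_DiffS"]], p[["m_Prog_DiffI"]],
              p[["m_Prog_ProS"]], p[["m_Prog_ProI"]])
  m_term <- c(p[["m_Term_DiffS"]], p[["m_Term_DiffI"]],
              p[["m_Term_ProS"]], p[["m_Term_ProI"]])
  d_pool <- numeric(4)
  for (k in 1:4) {
    fb <- exp(-(pools_in[k] / vol) / p[["c_hat"]])
    d_pool[k] <- m_prog[k] * fb * (lsk + cmp) + m_term[k] * fb * term
  }
  sw <- function(x) max(x, 0) / (max(x, 0) + 1e-2)
  d_scf <- -p[["K_SCF_consumption"]] * n / vol * sw(scf)
  d_gc <- -p[["K_GC_consumption"]] * n * sw(gc)

  c(LSK = d_lsk, CMP = d_cmp, Terminal = d_term,
    scf_conc = d_scf, gc_conc = d_gc,
    pool_DiffS = d_pool[1], pool_DiffI = d_pool[2],
    pool_ProS = d_pool[3], pool_ProI = d_pool[4])
}

oracle_rhs_five <- function(pop, env, p, vol_uL = 300) {
  vol <- vol_uL / 1000
  lt <- pop[["LT_HSC"]]; st <- pop[["ST_HSC"]]; mpp <- pop[["MPP"]]
  cmp <- pop[["CMP"]]; term <- pop[["Terminal"]]
  scf <- env[["scf_conc"]]; gc <- env[["gc_conc"]]

  rd <- oracle_ratio(env[["pool_DiffS"]], env[["pool_DiffI"]])
  f <- function(st_name) {
    p[[paste0("f_max_", st_name)]] /
      (1 + rd + p[[paste0("s_", st_name)]] * scf)
  }
  q <- function(st_name) p[[paste0("q_max_", st_name)]] * exp(-rd)
  dth <- function(st_name) {
    p[[paste0("death_max_", st_name)]] /
      (1 + p[[paste0("d_", st_name)]] * gc)
  }
  td <- p[["c_Term_DiffS"]] * term
  j_st <- p[["j_max_ST_HSCtoTerminal"]] * exp(-td / p[["t_hat"]])
  j_mpp <- p[["j_max_MPPtoTerminal"]] * exp(-td / p[["t_hat"]])

  lt_out <- (1 - q("LT_HSC")) * (1 - f("LT_HSC")) * p[["DR_LTtoST"]] * lt
  st_act <- (1 - q("ST_HSC")) * (1 - f("ST_HSC")) * st
  st_step <- st_act * (1 - j_st) * p[["DR_STtoMPP"]]
  st_jump <- st_act * j_st * p[["DR_STtoTerminal"]]
  mpp_act <- (1 - q("MPP")) * (1 - f("MPP")) * mpp
  mpp_step <- mpp_act * (1 - j_mpp) * p[["DR_MPPtoCMP"]]
  mpp_jump <- mpp_act * j_mpp * p[["DR_MPPtoTerminal"]]
  cmp_out <- (1 - f("CMP")) * p[["DR_CMPtoTerminal"]] * cmp

  d_lt <- (1 - q("LT_HSC")) * f("LT_HSC") * p[["PR_LT_HSC"]] * lt -
    lt_out - dth("LT_HSC") * lt
  d_st <- lt_out + (1 - q("ST_HSC")) * f("ST_HSC") * p[["PR_ST_HSC"]] * st -
    st_step - st_jump - dth("ST_HSC") * st
  d_mpp <- st_step + (1 - q("MPP")) * f("MPP") * p[["PR_MPP"]] * mpp -
    mpp_step - mpp_jump - dth("MPP") * mpp
  d_cmp <- mpp_step + f("CMP") * p[["PR_CMP"]] * cmp - cmp_out -
    dth("CMP") * cmp
  d_term <- st_jump + mpp_jump + cmp_out + p[["PR_Terminal"]] * term -
    dth("Terminal") * term

  n <- lt + st + mpp + cmp + term
  prog <- n - term
  pools <- c("DiffS", "DiffI", "ProS", "ProI")
  d_pool <- numeric(4)
  for (k in 1:4) {
    d_pool[k] <- p[[paste0("c_Prog_", pools[k])]] * prog +
      p[[paste0("c_Term_", pools[k])]] * term
  }
  sw <- function(x) max(x, 0) / (max(x, 0) + 1e-2)
  d_scf <- -p[["K_SCF_consumption"]] * n / vol * sw(scf)
  d_gc <- -p[["K_GC_consumption"]] * n * sw(gc)

  c(LT_HSC = d_lt, ST_HSC = d_st, MPP = d_mpp, CMP = d_cmp,
    Terminal = d_term, scf_conc = d_scf, gc_conc = d_gc,
    pool_DiffS = d_pool[1], pool_DiffI = d_pool[2],
    pool_ProS = d_pool[3], pool_ProI = d_pool[4])
}
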