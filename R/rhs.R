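#' Time derivatives of the differentiation model
#'
#' Evaluates the right-hand side of the coupled population/environment ODE
#' system for either hierarchy. Populations flow along the chain
#' (LSK -> CMP -> Terminal, or LT-HSC -> ST-HSC -> MPP -> CMP -> Terminal)
#' with self-renewal, quiescence, nutrient-dependent apoptosis and a direct
#' 'jump' into Terminal; the environment tracks SCF, the nutrient stock and
#' the four secreted biomolecule pools.
#'
#' Flow wiring: within the non-quiescent fraction `(1 - q)` of a state, the
#' self-renewing fraction `f` proliferates in place at rate `PR`, while the
#' remainder `(1 - f)` differentiates out; for jump-bearing states the
#' differentiation flux is split `(1 - j)` stepwise / `j` direct-to-Terminal,
#' each path with its own rate constant. Apoptosis is environmental and not
#' gated by quiescence. Consumption of SCF and nutrient is proportional to
#' total cell number and clamps at exhaustion; pools only accumulate (media
#' exchange resets them between integration segments).
#'
#' @param kind `"three_state"` or `"five_state"`.
#' @param pop Named numeric vector of cell counts, names = [hsc_states()].
#' @param env A [culture_environment()] row or a named vector with the same
#'   fields.
#' @param params An `hsc_params` object (matching `kind`).
#' @return A list with components `d_pop` (cells/day), `d_env` (per-day
#'   derivatives of `scf_conc`, `gc_conc` and the four pool amounts) and
#'   `kernels` (named vector of the instantaneous kernel values: `R_d`,
#'   `R_p`, `f_*`, `q_*`, `j_*`, `PR_*`, `death_*`, `T_d`).
#' @examples
#' p <- default_params("three_state")
#' hsc_derivatives("three_state", c(LSK = 5000, CMP = 0, Terminal = 0),
#'                 culture_environment(), p)$d_pop
#' @export
hsc_derivatives <- function(kind, pop, env, params) {
  kind <- match_kind(kind)
  stopifnot(inherits(params, "hsc_params"), params$kind == kind)
  states <- hsc_states(kind)
  pop <- unlist(pop)
  if (!all(states %in% names(pop))) {
    rlang::abort("`pop` must name every model state")
  }
  pop <- pop[states]
  if (inherits(env, "hsc_environment")) {
    vol <- env$media_volume
    env <- unlist(env[env_fields()])
  } else {
    env <- unlist(env)
    vol <- attr(env, "media_volume") %||% 300
    env <- env[env_fields()]
  }
  if (any(is.na(env))) rlang::abort("`env` must carry all environment fields")
  y <- c(pop, env)
  res <- rhs_core(kind, y, params$values, vol_mL = vol / 1000)
  list(
    d_pop = res$dy[states],
    d_env = res$dy[env_fields()],
    kernels = res$kernels
  )
}

# core derivative evaluation on the raw ODE state vector.
# y: populations (model states) followed by env_fields(); p: named parameters.
rhs_core <- function(kind, y, p, vol_mL) {
  if (any(!is.finite(y))) {
    bad <- names(y)[!is.finite(y)][1]
    rlang::abort(paste0("non-finite ODE state in component `", bad, "`"))
  }
  y <- pmax(y, 0)  # solver round-off guard; physical states are non-negative
  scf <- y[["scf_conc"]]
  gc <- y[["gc_conc"]]
  pools <- y[c("pool_DiffS", "pool_DiffI", "pool_ProS", "pool_ProI")]
  R_d <- pool_ratio(pools[["pool_DiffS"]], pools[["pool_DiffI"]])
  R_p <- pool_ratio(pools[["pool_ProS"]], pools[["pool_ProI"]])

  if (kind == "three_state") {
    lsk <- y[["LSK"]]; cmp <- y[["CMP"]]; term <- y[["Terminal"]]
    n_tot <- lsk + cmp + term
    prog <- lsk + cmp

    de <- p[paste0("death_max_", c("LSK", "CMP", "Terminal"))] /
      (1 + p[paste0("d_", c("LSK", "CMP", "Terminal"))] * gc)
    names(de) <- c("LSK", "CMP", "Terminal")
    PR <- p[paste0("PR_max_", c("LSK", "CMP", "Terminal"))] *
      (1 - exp(-scf * R_p / p[["s_hat"]]))
    names(PR) <- c("LSK", "CMP", "Terminal")
    f_L <- p[["f_max_LSK"]] / (1 + R_d + p[["s_LSK"]] * scf)
    f_C <- p[["f_max_CMP"]] / (1 + R_d + p[["s_CMP"]] * scf)
    q <- p[["q_max_LSK"]] * exp(-R_d)
    T_d <- p[["m_Term_DiffS"]] * term
    j <- p[["j_max_LSK"]] * exp(-T_d / p[["t_hat"]])
    a <- 1 - q

    d_lsk <- a * f_L * PR[["LSK"]] * lsk -
      a * (1 - f_L) * ((1 - j) * p[["DR_LSKtoCMP"]] +
                         j * p[["DR_LSKtoTerminal"]]) * lsk -
      de[["LSK"]] * lsk
    d_cmp <- a * (1 - f_L) * (1 - j) * p[["DR_LSKtoCMP"]] * lsk +
      f_C * PR[["CMP"]] * cmp -
      (1 - f_C) * p[["DR_CMPtoTerminal"]] * cmp -
      de[["CMP"]] * cmp
    d_term <- a * (1 - f_L) * j * p[["DR_LSKtoTerminal"]] * lsk +
      (1 - f_C) * p[["DR_CMPtoTerminal"]] * cmp +
      PR[["Terminal"]] * term -
      de[["Terminal"]] * term

    # secretion with product feedback: rate decays with the pool's own level
    conc <- pools / vol_mL
    c_prog <- p[paste0("m_Prog_", c("DiffS", "DiffI", "ProS", "ProI"))] *
      exp(-conc / p[["c_hat"]])
    c_term <- p[paste0("m_Term_", c("DiffS", "DiffI", "ProS", "ProI"))] *
      exp(-conc / p[["c_hat"]])
    d_pools <- unname(c_prog) * prog + unname(c_term) * term

    d_scf <- -p[["K_SCF_consumption"]] * n_tot / vol_mL * depletion_switch(scf)
    d_gc <- -p[["K_GC_consumption"]] * n_tot * depletion_switch(gc)

    dy <- c(LSK = unname(d_lsk), CMP = unname(d_cmp),
            Terminal = unname(d_term),
            scf_conc = d_scf, gc_conc = d_gc,
            pool_DiffS = d_pools[[1]], pool_DiffI = d_pools[[2]],
            pool_ProS = d_pools[[3]], pool_ProI = d_pools[[4]])
    kernels <- c(
      R_d = R_d, R_p = R_p, T_d = unname(T_d),
      f_LSK = unname(f_L), f_CMP = unname(f_C),
      q_LSK = unname(q), j_LSK = unname(j),
      PR_LSK = PR[["LSK"]], PR_CMP = PR[["CMP"]],
      PR_Terminal = PR[["Terminal"]],
      death_LSK = de[["LSK"]], death_CMP = de[["CMP"]],
      death_Terminal = de[["Terminal"]]
    )
    return(list(dy = dy, kernels = kernels))
  }

  # five_state
  st <- c("LT_HSC", "ST_HSC", "MPP", "CMP", "Terminal")
  n <- y[st]
  n_tot <- sum(n)
  prog <- n_tot - n[["Terminal"]]

  de <- p[paste0("death_max_", st)] / (1 + p[paste0("d_", st)] * gc)
  names(de) <- st
  PR <- p[paste0("PR_", st)]
  names(PR) <- st
  f <- p[paste0("f_max_", st[1:4])] /
    (1 + R_d + p[paste0("s_", st[1:4])] * scf)
  names(f) <- st[1:4]
  q <- p[paste0("q_max_", st[1:3])] * exp(-R_d)
  names(q) <- st[1:3]
  a <- 1 - q
  T_d <- p[["c_Term_DiffS"]] * n[["Terminal"]]
  j_st <- p[["j_max_ST_HSCtoTerminal"]] * exp(-T_d / p[["t_hat"]])
  j_mpp <- p[["j_max_MPPtoTerminal"]] * exp(-T_d / p[["t_hat"]])

  out_lt <- a[["LT_HSC"]] * (1 - f[["LT_HSC"]]) * p[["DR_LTtoST"]] *
    n[["LT_HSC"]]
  out_st_step <- a[["ST_HSC"]] * (1 - f[["ST_HSC"]]) * (1 - j_st) *
    p[["DR_STtoMPP"]] * n[["ST_HSC"]]
  out_st_jump <- a[["ST_HSC"]] * (1 - f[["ST_HSC"]]) * j_st *
    p[["DR_STtoTerminal"]] * n[["ST_HSC"]]
  out_mpp_step <- a[["MPP"]] * (1 - f[["MPP"]]) * (1 - j_mpp) *
    p[["DR_MPPtoCMP"]] * n[["MPP"]]
  out_mpp_jump <- a[["MPP"]] * (1 - f[["MPP"]]) * j_mpp *
    p[["DR_MPPtoTerminal"]] * n[["MPP"]]
  out_cmp <- (1 - f[["CMP"]]) * p[["DR_CMPtoTerminal"]] * n[["CMP"]]

  d_lt <- a[["LT_HSC"]] * f[["LT_HSC"]] * PR[["LT_HSC"]] * n[["LT_HSC"]] -
    out_lt - de[["LT_HSC"]] * n[["LT_HSC"]]
  d_st <- out_lt +
    a[["ST_HSC"]] * f[["ST_HSC"]] * PR[["ST_HSC"]] * n[["ST_HSC"]] -
    out_st_step - out_st_jump - de[["ST_HSC"]] * n[["ST_HSC"]]
  d_mpp <- out_st_step +
    a[["MPP"]] * f[["MPP"]] * PR[["MPP"]] * n[["MPP"]] -
    out_mpp_step - out_mpp_jump - de[["MPP"]] * n[["MPP"]]
  d_cmp <- out_mpp_step + f[["CMP"]] * PR[["CMP"]] * n[["CMP"]] -
    out_cmp - de[["CMP"]] * n[["CMP"]]
  d_term <- out_st_jump + out_mpp_jump + out_cmp +
    PR[["Terminal"]] * n[["Terminal"]] - de[["Terminal"]] * n[["Terminal"]]

  # constant secretion in the five-state variant
  c_prog <- p[paste0("c_Prog_", c("DiffS", "DiffI", "ProS", "ProI"))]
  c_term <- p[paste0("c_Term_", c("DiffS", "DiffI", "ProS", "ProI"))]
  d_pools <- unname(c_prog) * prog + unname(c_term) * n[["Terminal"]]

  d_scf <- -p[["K_SCF_consumption"]] * n_tot / vol_mL * depletion_switch(scf)
  d_gc <- -p[["K_GC_consumption"]] * n_tot * depletion_switch(gc)

  dy <- c(LT_HSC = unname(d_lt), ST_HSC = unname(d_st), MPP = unname(d_mpp),
          CMP = unname(d_cmp), Terminal = unname(d_term),
          scf_conc = d_scf, gc_conc = d_gc,
          pool_DiffS = d_pools[[1]], pool_DiffI = d_pools[[2]],
          pool_ProS = d_pools[[3]], pool_ProI = d_pools[[4]])
  kernels <- c(
    R_d = R_d, R_p = R_p, T_d = unname(T_d),
    f_LT_HSC = f[["LT_HSC"]], f_ST_HSC = f[["ST_HSC"]],
    f_MPP = f[["MPP"]], f_CMP = f[["CMP"]],
    q_LT_HSC = q[["LT_HSC"]], q_ST_HSC = q[["ST_HSC"]], q_MPP = q[["MPP"]],
    j_ST_HSC = unname(j_st), j_MPP = unname(j_mpp),
    PR_LT_HSC = PR[["LT_HSC"]], PR_ST_HSC = PR[["ST_HSC"]],
    PR_MPP = PR[["MPP"]], PR_CMP = PR[["CMP"]],
    PR_Terminal = PR[["Terminal"]],
    death_LT_HSC = de[["LT_HSC"]], death_ST_HSC = de[["ST_HSC"]],
    death_MPP = de[["MPP"]], death_CMP = de[["CMP"]],
    death_Terminal = de[["Terminal"]]
  )
  list(dy = dy, kernels = kernels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smooth cutoff for consumable stocks: consumption scales by x / (x + k) so
# it vanishes continuously at exhaustion instead of switching discontinuously
# (keeps the RHS Lipschitz for the adaptive solver). k is far below working
# concentrations (100 ng/mL SCF, 10 mM nutrient), so the switch only acts in
# the last ~0.01 unit of stock.
depletion_switch <- function(x, k = 1e-2) {
  x <- max(x, 0)
  x / (x + k)
}
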