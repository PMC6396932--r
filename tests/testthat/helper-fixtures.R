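# Programmatic fixtures shared across test files.

# random but admissible parameter set (fractions <= 1, everything >= 0)
random_params <- function(kind, seed) {
  set.seed(seed)
  nm <- hscdyn:::param_names(kind)
  vals <- stats::setNames(numeric(length(nm)), nm)
  for (n in nm) {
    vals[[n]] <-
      if (grepl("^(f_max|q_max|j_max)", n)) stats::runif(1, 0.05, 1) else
      if (grepl("^(m_|c_Prog|c_Term)", n)) 10^stats::runif(1, -7, -3) else
      if (grepl("^K_", n)) 10^stats::runif(1, -7, -4) else
      if (n %in% c("c_hat", "s_hat", "t_hat")) stats::runif(1, 0.5, 5) else
      if (grepl("^s_", n)) stats::runif(1, 0, 0.05) else
      stats::runif(1, 0.05, 3)
  }
  states <- hsc_states(kind)
  init <- stats::setNames(stats::runif(length(states), 0, 5000), states)
  hsc_params(kind, vals, init)
}

random_state <- function(kind, seed) {
  set.seed(seed)
  states <- hsc_states(kind)
  list(
    pop = stats::setNames(stats::runif(length(states), 0, 1e5), states),
    env = culture_environment(
      scf_conc = stats::runif(1, 0, 100),
      gc_conc = stats::runif(1, 0, 10),
      pool_DiffS = stats::runif(1, 0, 5),
      pool_DiffI = stats::runif(1, 0, 5),
      pool_ProS = stats::runif(1, 0, 5),
      pool_ProI = stats::runif(1, 0, 5)
    )
  )
}

# parameter set with every rate zeroed (populations frozen)
zero_params <- function(kind) {
  nm <- hscdyn:::param_names(kind)
  vals <- stats::setNames(rep(0, length(nm)), nm)
  vals[c("c_hat", "s_hat", "t_hat")[c("c_hat", "s_hat", "t_hat") %in% nm]] <- 1
  states <- hsc_states(kind)
  init <- stats::setNames(rep(0, length(states)), states)
  init[[states[1]]] <- 1000
  hsc_params(kind, vals, init)
}

# pure exponential toy: an isolated Terminal compartment proliferating at a
# constant rate, nothing else active
exp_toy_params <- function(rate = 0.3, n0 = 1000) {
  p <- zero_params("five_state")
  p$values[["PR_Terminal"]] <- rate
  p$init[] <- 0
  p$init[["Terminal"]] <- n0
  validate_params(p)
}
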