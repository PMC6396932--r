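#' Feedback ratios of stimulator vs inhibitor pools
#'
#' The secreted biomolecule pools act on the kinetics only through two
#' dimensionless ratios: the differentiation drive `R_d = DiffS / DiffI` and
#' the proliferation drive `R_p = ProS / ProI`. A zero inhibitor pool is
#' floored at `eps` (ng) so the ratio stays finite; a zero stimulator pool
#' gives a ratio of exactly 0, which covers the empty culture at t = 0 where
#' all four pools are zero.
#'
#' @param env A [culture_environment()] row (or anything with the four
#'   `pool_*` columns).
#' @param eps Floor (ng) applied to a zero inhibitor pool.
#' @return A one-row tibble with columns `R_d` and `R_p`.
#' @examples
#' feedback_ratios(culture_environment(pool_DiffS = 2, pool_DiffI = 1))
#' @export
feedback_ratios <- function(env, eps = 1e-9) {
  check_nonneg(c(env$pool_DiffS, env$pool_DiffI, env$pool_ProS, env$pool_ProI),
               "pool amounts")
  tibble::tibble(
    R_d = pool_ratio(env$pool_DiffS, env$pool_DiffI, eps),
    R_p = pool_ratio(env$pool_ProS, env$pool_ProI, eps)
  )
}

pool_ratio <- function(num, den, eps = 1e-9) {
  ifelse(num == 0, 0, num / pmax(den, eps))
}

#' Rate-law kernels of the feedback model
#'
#' Closed-form kernels shared by both model variants. All are elementwise
#' vectorized and validate their domains.
#'
#' * `secretion_rate()`: per-cell secretion under product feedback,
#'   `m * exp(-conc / c_hat)` (ng/cell/day). Used by the 3-state model; the
#'   5-state model uses constant secretion.
#' * `death_rate()`: nutrient-dependent apoptosis,
#'   `death_max / (1 + d * gc_conc)` (1/day) — maximal when the nutrient stock
#'   is exhausted.
#' * `self_renewal_fraction()`: modified Monod form
#'   `f_max / (1 + R_d + s * scf_conc)`, always <= `f_max`.
#' * `proliferation_rate()`: saturating activation
#'   `PR_max * (1 - exp(-scf_conc * R_p / s_hat))` (1/day); zero without SCF
#'   or without proliferation stimulators.
#' * `quiescent_fraction()`: `q_max * exp(-R_d)` — quiescence collapses as
#'   differentiation stimulation rises.
#' * `jump_fraction()`: `j_max * exp(-T_d / t_hat)` — the fraction of the
#'   differentiation flux that bypasses CMP straight into Terminal, under
#'   negative feedback from the Terminal-derived signal `T_d`.
#'
#' @param m Base secretion rate, ng/cell/day.
#' @param pool_conc Concentration of the secreted pool, ng/mL.
#' @param c_hat Reference pool concentration (ng/mL) nondimensionalizing the
#'   secretion feedback exponential.
#' @param death_max Maximum apoptosis rate, 1/day.
#' @param d Nutrient protection constant, 1/mM.
#' @param gc_conc Nutrient concentration, mM.
#' @param f_max Maximum self-renewing fraction, in `[0, 1]`.
#' @param s SCF sensitivity of self-renewal, mL/ng.
#' @param R_d,R_p Feedback ratios from [feedback_ratios()].
#' @param scf_conc SCF concentration, ng/mL.
#' @param PR_max Maximum proliferation rate, 1/day.
#' @param s_hat Reference SCF scale (ng/mL) for the proliferation exponential.
#' @param q_max Maximum quiescent fraction, in `[0, 1]`.
#' @param j_max Maximum jump fraction, in `[0, 1]`.
#' @param T_d Terminal-feedback signal (dimensionless after `t_hat` scaling).
#' @param t_hat Reference scale of the Terminal-feedback signal.
#' @return Numeric vector of rates (1/day) or fractions (dimensionless).
#' @examples
#' secretion_rate(0.01, 0)
#' death_rate(0.2, 0.5, 10)
#' self_renewal_fraction(0.8, 0.01, R_d = 1, scf_conc = 100)
#' @name kernels
NULL

#' @rdname kernels
#' @export
secretion_rate <- function(m, pool_conc, c_hat = 1) {
  check_nonneg(m, "`m`")
  check_nonneg(pool_conc, "`pool_conc`")
  m * exp(-pool_conc / c_hat)
}

#' @rdname kernels
#' @export
death_rate <- function(death_max, d, gc_conc) {
  check_nonneg(death_max, "`death_max`")
  check_nonneg(d, "`d`")
  check_nonneg(gc_conc, "`gc_conc`")
  death_max / (1 + d * gc_conc)
}

#' @rdname kernels
#' @export
self_renewal_fraction <- function(f_max, s, R_d, scf_conc) {
  check_fraction(f_max, "`f_max`")
  check_nonneg(s, "`s`")
  check_nonneg(R_d, "`R_d`")
  check_nonneg(scf_conc, "`scf_conc`")
  f_max / (1 + R_d + s * scf_conc)
}

#' @rdname kernels
#' @export
proliferation_rate <- function(PR_max, scf_conc, R_p, s_hat = 1) {
  check_nonneg(PR_max, "`PR_max`")
  check_nonneg(scf_conc, "`scf_conc`")
  check_nonneg(R_p, "`R_p`")
  PR_max * (1 - exp(-scf_conc * R_p / s_hat))
}

#' @rdname kernels
#' @export
quiescent_fraction <- function(q_max, R_d) {
  check_fraction(q_max, "`q_max`")
  check_nonneg(R_d, "`R_d`")
  q_max * exp(-R_d)
}

#' @rdname kernels
#' @export
jump_fraction <- function(j_max, T_d, t_hat = 1) {
  check_fraction(j_max, "`j_max`")
  check_nonneg(T_d, "`T_d`")
  j_max * exp(-T_d / t_hat)
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    rlang::abort(paste0(what, " must be finite and non-negative"))
  }
  invisible(x)
}

check_fraction <- function(x, what) {
  check_nonneg(x, what)
  if (any(x > 1)) {
    rlang::abort(paste0(what, " must lie in [0, 1]"))
  }
  invisible(x)
}
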