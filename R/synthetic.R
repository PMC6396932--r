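#' Replicate-noise model for synthetic observations
#'
#' Flow-cytometry-style counts are positive and span four orders of
#' magnitude, so replicate scatter is modelled as lognormal multiplicative
#' noise with a fixed coefficient of variation: each replicate is
#' `count * L` where `L` is lognormal with mean 1 and CV `cv`. `kind =
#' "none"` returns the exact model values with zero SEM.
#'
#' @param kind `"lognormal_multiplicative"` or `"none"`.
#' @param cv Coefficient of variation of a single replicate.
#' @param n_replicates Replicates per state and time point.
#' @param seed Integer seed for replicate draws.
#' @return A list of class `hsc_noise`.
#' @export
noise_model <- function(kind = c("lognormal_multiplicative", "none"),
                        cv = 0.15, n_replicates = 3, seed = 1) {
  kind <- match.arg(kind)
  if (cv < 0) rlang::abort("`cv` must be >= 0")
  if (n_replicates < 1) rlang::abort("`n_replicates` must be >= 1")
  structure(list(kind = kind, cv = cv, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "hsc_noise")
}

#' Generate synthetic observed cell-count time series
#'
#' Simulates a culture, samples the populations at the requested times
#' (default the measurement design: 0.5, 1, 2, 4, 7 and 9 days) and draws
#' replicate counts under the noise model, reporting the replicate mean and
#' its standard error per state and time. The result is a stand-in for the
#' FACS subset counts an actual culture experiment would produce.
#'
#' @param kind `"three_state"` or `"five_state"`.
#' @param params An `hsc_params`; default the calibrated set.
#' @param sched An [exchange_schedule()].
#' @param times Sampling times, days.
#' @param noise A [noise_model()].
#' @param init Initial populations; default from `params`.
#' @return A tibble `(time_day, state, count, sem, n_rep)` where `count` is
#'   the replicate mean.
#' @examples
#' generate_observations("three_state", noise = noise_model("none"))
#' @export
generate_observations <- function(kind, params = default_params(kind),
                                  sched = exchange_schedule(),
                                  times = c(0.5, 1, 2, 4, 7, 9),
                                  noise = noise_model(), init = NULL) {
  kind <- match_kind(kind)
  stopifnot(inherits(noise, "hsc_noise"))
  traj <- simulate_culture(kind, params, sched, init = init,
                           sample_times = times)
  exact <- sample_trajectory(traj, times)
  if (noise$kind == "none") {
    return(dplyr::mutate(exact, sem = 0, n_rep = 1L))
  }
  sdlog <- sqrt(log(1 + noise$cv^2))
  meanlog <- -sdlog^2 / 2  # unit-mean multiplier
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(noise$seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  n <- noise$n_replicates
  reps <- purrr::map_dfr(seq_len(nrow(exact)), function(i) {
    draws <- exact$count[i] *
      stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    tibble::tibble(
      time_day = exact$time_day[i], state = exact$state[i],
      count = mean(draws),
      sem = stats::sd(draws) / sqrt(n),
      n_rep = as.integer(n)
    )
  })
  reps
}

#' Packaged reference culture scenarios
#'
#' Self-contained bundles mirroring the experimental arms: the 3-state model
#' under 2-, 5- and 10-day media exchange (10-day means no exchange within
#' the 9-day horizon) and the 5-state model under 2-day exchange. Each bundle
#' carries the calibrated parameters, the schedule, the sampling design and a
#' synthetic observed dataset regenerated from a fixed, documented seed.
#'
#' @param name One of `"three_state_2d"`, `"three_state_5d"`,
#'   `"three_state_10d"`, `"five_state_2d"`.
#' @return A list of class `hsc_scenario` with elements `name`, `kind`,
#'   `params`, `sched`, `times`, `noise`, `observed`.
#' @examples
#' sc <- reference_experiment("three_state_10d")
#' exchange_times(sc$sched)
#' @export
reference_experiment <- function(name) {
  catalog <- list(
    three_state_2d  = list(kind = "three_state", frequency = 2,  seed = 101L),
    three_state_5d  = list(kind = "three_state", frequency = 5,  seed = 102L),
    three_state_10d = list(kind = "three_state", frequency = 10, seed = 103L),
    five_state_2d   = list(kind = "five_state",  frequency = 2,  seed = 105L)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(catalog)) {
    rlang::abort(paste0(
      "unknown scenario; choose one of ",
      paste0('"', names(catalog), '"', collapse = ", ")
    ))
  }
  cfg <- catalog[[name]]
  params <- default_params(cfg$kind)
  sched <- exchange_schedule(frequency = cfg$frequency)
  times <- c(0.5, 1, 2, 4, 7, 9)
  noise <- noise_model("lognormal_multiplicative", cv = 0.15,
                       n_replicates = 3, seed = cfg$seed)
  observed <- generate_observations(cfg$kind, params, sched, times, noise)
  structure(
    list(name = name, kind = cfg$kind, params = params, sched = sched,
         times = times, noise = noise, observed = observed),
    class = "hsc_scenario"
  )
}

#' @export
print.hsc_scenario <- function(x, ...) {
  cat(sprintf(
    "<hsc_scenario> %s: %s model, exchange every %g d, seed %d\n",
    x$name, x$kind, x$sched$frequency, x$noise$seed
  ))
  invisible(x)
}
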