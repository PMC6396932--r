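#' Media-exchange schedule
#'
#' Full media exchanges are performed every `frequency` days up to `horizon`.
#' An exchange restores the SCF and nutrient stocks to their input
#' concentrations and discards the secreted biomolecule pools; cells stay in
#' the well. A frequency at or beyond the horizon means the media are never
#' exchanged.
#'
#' @param frequency Days between exchanges (e.g. 2, 5, 10).
#' @param horizon Culture duration, days.
#' @param scf_input SCF concentration of fresh media, ng/mL.
#' @param gc_input Nutrient concentration of fresh media, mM.
#' @param media_volume Well volume, uL (constant).
#' @return A list of class `hsc_schedule`.
#' @examples
#' exchange_times(exchange_schedule(frequency = 2))
#' @export
exchange_schedule <- function(frequency = 2, horizon = 9, scf_input = 100,
                              gc_input = 10, media_volume = 300) {
  if (!is.finite(frequency) || frequency <= 0) {
    rlang::abort("`frequency` must be a positive number of days")
  }
  if (!is.finite(horizon) || horizon <= 0) {
    rlang::abort("`horizon` must be a positive number of days")
  }
  check_nonneg(scf_input, "`scf_input`")
  check_nonneg(gc_input, "`gc_input`")
  if (media_volume <= 0) rlang::abort("`media_volume` must be positive")
  structure(
    list(frequency = frequency, horizon = horizon, scf_input = scf_input,
         gc_input = gc_input, media_volume = media_volume),
    class = "hsc_schedule"
  )
}

#' @rdname exchange_schedule
#' @param sched An `hsc_schedule`.
#' @export
exchange_times <- function(sched) {
  stopifnot(inherits(sched, "hsc_schedule"))
  if (sched$frequency > sched$horizon) return(numeric(0))
  seq(sched$frequency, sched$horizon, by = sched$frequency)
}

#' Apply one full media exchange to an environment
#'
#' Resets SCF and nutrient to the fresh-media inputs and zeroes all four
#' secreted pools; the media volume and (implicitly) the cells are untouched.
#' Idempotent: exchanging twice equals exchanging once.
#'
#' @param env A [culture_environment()] row.
#' @param sched An [exchange_schedule()].
#' @return The refreshed `hsc_environment`.
#' @examples
#' apply_media_exchange(culture_environment(scf_conc = 3, pool_DiffI = 7),
#'                      exchange_schedule())
#' @export
apply_media_exchange <- function(env, sched) {
  stopifnot(inherits(env, "hsc_environment"), inherits(sched, "hsc_schedule"))
  culture_environment(
    scf_conc = sched$scf_input, gc_conc = sched$gc_input,
    media_volume = env$media_volume,
    pool_DiffS = 0, pool_DiffI = 0, pool_ProS = 0, pool_ProI = 0
  )
}

#' Simulate a media-exchange culture
#'
#' Integrates the chosen hierarchy from seeding to `sched$horizon`, applying
#' an instantaneous full media exchange at every multiple of the exchange
#' frequency. Integration uses `deSolve::lsoda` (adaptive, stiff-capable);
#' exchanges are handled as solver events between integration segments, which
#' is exact for a constant-volume full exchange.
#'
#' @param kind `"three_state"` or `"five_state"`.
#' @param params An `hsc_params` object; defaults to the packaged calibrated
#'   set for `kind`.
#' @param sched An [exchange_schedule()]; default 2-day exchanges over 9 days.
#' @param init Named numeric vector of seeded cells per state; defaults to
#'   the parameter set's `init` (5000 LSK-gate cells).
#' @param env0 Starting [culture_environment()]; defaults to fresh media
#'   (100 ng/mL SCF, 10 mM nutrient, empty pools).
#' @param sample_times Extra times (days) guaranteed to be on the output grid.
#' @param grid_by Dense output spacing, days.
#' @param rtol,atol Solver tolerances.
#' @return An `hsc_trajectory`: a tibble with one row per grid time carrying
#'   the populations (cells), the environment, and the instantaneous kernel
#'   values, with the run configuration in attributes.
#' @examples
#' traj <- simulate_culture("three_state")
#' dplyr::slice_tail(tidy(traj), n = 3)
#' @export
simulate_culture <- function(kind, params = default_params(kind),
                             sched = exchange_schedule(),
                             init = NULL, env0 = NULL,
                             sample_times = NULL, grid_by = 0.05,
                             rtol = 1e-8, atol = 1e-4) {
  kind <- match_kind(kind)
  params <- validate_params(params)
  stopifnot(inherits(sched, "hsc_schedule"))
  states <- hsc_states(kind)
  if (is.null(init)) init <- params$init
  init <- unlist(init)[states]
  if (any(is.na(init)) || any(init < 0)) {
    rlang::abort("`init` must give a non-negative count for every state")
  }
  if (is.null(env0)) {
    env0 <- culture_environment(
      scf_conc = sched$scf_input, gc_conc = sched$gc_input,
      media_volume = sched$media_volume
    )
  }
  stopifnot(inherits(env0, "hsc_environment"))

  ev_times <- exchange_times(sched)
  ev_times <- ev_times[ev_times < sched$horizon]  # event at horizon is moot
  times <- sort(unique(c(
    seq(0, sched$horizon, by = grid_by), sched$horizon, ev_times,
    sample_times
  )))
  if (!is.null(sample_times) &&
      (any(sample_times < 0) || any(sample_times > sched$horizon))) {
    rlang::abort("`sample_times` must lie within [0, horizon]")
  }

  y0 <- c(init, unlist(culture_env_vector(env0)))
  parms <- list(kind = kind, p = params$values,
                vol_mL = sched$media_volume / 1000)
  deriv_fun <- function(t, y, parms) {
    res <- rhs_core(parms$kind, y, parms$p, parms$vol_mL)
    list(res$dy, res$kernels)
  }
  event_fun <- function(t, y, parms) {
    y[["scf_conc"]] <- sched$scf_input
    y[["gc_conc"]] <- sched$gc_input
    y[c("pool_DiffS", "pool_DiffI", "pool_ProS", "pool_ProI")] <- 0
    y
  }
  sol <- if (length(ev_times) > 0) {
    deSolve::ode(y = y0, times = times, func = deriv_fun, parms = parms,
                 method = "lsoda", rtol = rtol, atol = atol, maxsteps = 2e4,
                 events = list(func = event_fun, time = ev_times))
  } else {
    deSolve::ode(y = y0, times = times, func = deriv_fun, parms = parms,
                 method = "lsoda", rtol = rtol, atol = atol, maxsteps = 2e4)
  }
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    rlang::abort(paste0(
      "integration failed (lsoda istate ", attr(sol, "istate")[1],
      ") near t = ", max(sol[, "time"], na.rm = TRUE), " days"
    ))
  }
  sol <- as.data.frame(sol)
  if (any(!is.finite(as.matrix(sol)))) {
    bad <- names(sol)[colSums(!is.finite(as.matrix(sol))) > 0][1]
    rlang::abort(paste0("non-finite trajectory values in `", bad, "`"))
  }
  # round tiny solver negatives up to exact zero
  phys <- c(states, env_fields())
  sol[phys] <- lapply(sol[phys], pmax, 0)
  # report the post-exchange (right-continuous) state at event rows: the
  # exchange is instantaneous, so the refreshed environment is the value the
  # culture actually continues from; kernels are recomputed to match
  for (te in ev_times) {
    i <- which(sol$time == te)
    sol[i, "scf_conc"] <- sched$scf_input
    sol[i, "gc_conc"] <- sched$gc_input
    sol[i, c("pool_DiffS", "pool_DiffI", "pool_ProS", "pool_ProI")] <- 0
    yi <- stats::setNames(as.numeric(sol[i, c(states, env_fields())]),
                          c(states, env_fields()))
    ki <- rhs_core(kind, yi, params$values, sched$media_volume / 1000)$kernels
    sol[i, names(ki)] <- as.list(ki)
  }
  out <- tibble::as_tibble(sol)
  names(out)[names(out) == "time"] <- "time_day"
  attr(out, "kind") <- kind
  attr(out, "params") <- params
  attr(out, "schedule") <- sched
  attr(out, "init") <- init
  class(out) <- c("hsc_trajectory", class(out))
  out
}

culture_env_vector <- function(env) {
  stats::setNames(as.numeric(env[1, env_fields()]), env_fields())
}

#' Tidy a trajectory into long format
#'
#' @param x An `hsc_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time_day`, `state`, `count`.
#' @export
tidy.hsc_trajectory <- function(x, ...) {
  states <- hsc_states(attr(x, "kind"))
  out <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), dplyr::all_of(c("time_day", states))),
    cols = dplyr::all_of(states), names_to = "state", values_to = "count"
  )
  out$state <- factor(out$state, levels = states)
  dplyr::arrange(out, .data$state, .data$time_day)
}

#' One-line summary of a simulated trajectory
#'
#' @param x An `hsc_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: variant, horizon, exchange frequency, number of
#'   grid points, final total cell count and peak Terminal count.
#' @importFrom generics glance
#' @export
glance.hsc_trajectory <- function(x, ...) {
  states <- hsc_states(attr(x, "kind"))
  sched <- attr(x, "schedule")
  tibble::tibble(
    kind = attr(x, "kind"),
    horizon_day = sched$horizon,
    exchange_every_day = sched$frequency,
    n_grid = nrow(x),
    total_final = sum(as.numeric(x[nrow(x), states])),
    terminal_peak = max(x$Terminal)
  )
}

#' @export
print.hsc_trajectory <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<hsc_trajectory> %s, %g days, exchange every %g d, %d grid points\n",
    g$kind, g$horizon_day, g$exchange_every_day, g$n_grid
  ))
  NextMethod()
}

#' Interpolate a trajectory at arbitrary times
#'
#' Monotone cubic (Fritsch--Carlson) interpolation of each state's count on
#' the dense output grid; exact at grid points, no overshoot between them.
#'
#' @param traj An `hsc_trajectory`.
#' @param times Numeric vector of times (days) within the simulated horizon.
#' @return A tibble with columns `time_day`, `state`, `count`.
#' @examples
#' traj <- simulate_culture("three_state")
#' sample_trajectory(traj, c(0.5, 1, 2, 4, 7, 9))
#' @export
sample_trajectory <- function(traj, times) {
  stopifnot(inherits(traj, "hsc_trajectory"))
  rng <- range(traj$time_day)
  if (any(times < rng[1]) || any(times > rng[2])) {
    rlang::abort(sprintf(
      "`times` must lie within the simulated range [%g, %g] days",
      rng[1], rng[2]
    ))
  }
  states <- hsc_states(attr(traj, "kind"))
  grid <- traj$time_day
  purrr::map_dfr(states, function(st) {
    fn <- stats::splinefun(grid, traj[[st]], method = "monoH.FC")
    tibble::tibble(time_day = times, state = st, count = pmax(fn(times), 0))
  }) |>
    dplyr::mutate(state = factor(.data$state, levels = states)) |>
    dplyr::arrange(.data$state, .data$time_day)
}

#' Plot a simulated trajectory
#'
#' Population time courses on a log10 axis, one line per state, with media
#' exchanges marked.
#'
#' @param object An `hsc_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.hsc_trajectory <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::filter(long, .data$count > 0)
  ev <- exchange_times(attr(object, "schedule"))
  ev <- ev[ev < attr(object, "schedule")$horizon]
  gg <- ggplot2::ggplot(long,
    ggplot2::aes(x = .data$time_day, y = .data$count,
                 colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "cells", colour = NULL) +
    ggplot2::theme_minimal()
  if (length(ev) > 0) {
    gg <- gg + ggplot2::geom_vline(xintercept = ev, linetype = "dotted",
                                   colour = "grey50")
  }
  gg
}
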