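#' Local parameter sensitivity
#'
#' One-at-a-time local sensitivity of each cell state's count to a kinetic
#' parameter: the parameter is raised by `delta_frac` (default 1%), the
#' culture re-simulated, and the per-time sensitivity computed as
#' `S_t = [(O'(t) - O(t)) / O(t)] / delta_frac`, with `O` the state's count.
#' The summary statistic `S` is the average of `S_t` over the evaluation
#' times (signed by default). Times where the baseline count is zero leave
#' the sensitivity undefined and are excluded with a warning. `side =
#' "central"` uses a symmetric perturbation instead of the one-sided +1%.
#'
#' Initial populations can be perturbed too, as pseudo-parameters named
#' `init_<state>` (e.g. `"init_LSK"`).
#'
#' `temporal_sensitivity()` returns the per-time series; `local_sensitivity()`
#' its time average.
#'
#' @param kind `"three_state"` or `"five_state"`.
#' @param params An `hsc_params`; defaults to the calibrated set.
#' @param param_name Name of the parameter to perturb (positive base value).
#' @param sched An [exchange_schedule()].
#' @param delta_frac Relative perturbation (default 0.01 = 1%).
#' @param eval_times Evaluation times, days.
#' @param states States to report; default all.
#' @param side `"forward"` or `"central"` differencing.
#' @param average `"signed"` (default) or `"absolute"` time-averaging.
#' @return `temporal_sensitivity()`: tibble `(parameter, state, time_day,
#'   S_t)`; `local_sensitivity()`: tibble `(parameter, state, S, n_times)`.
#' @examples
#' local_sensitivity("three_state", param_name = "PR_max_Terminal")
#' @export
temporal_sensitivity <- function(kind, params = default_params(kind),
                                 param_name, sched = exchange_schedule(),
                                 delta_frac = 0.01,
                                 eval_times = c(0.5, 1, 2, 4, 7, 9),
                                 states = hsc_states(kind),
                                 side = c("forward", "central")) {
  kind <- match_kind(kind)
  side <- match.arg(side)
  stopifnot(length(param_name) == 1L, delta_frac > 0)
  states <- match.arg(states, hsc_states(kind), several.ok = TRUE)

  base_counts <- sens_counts(kind, params, sched, eval_times, param_name, 0)
  up <- sens_counts(kind, params, sched, eval_times, param_name, delta_frac)
  if (side == "forward") {
    num <- (up$count - base_counts$count) / base_counts$count
    denom <- delta_frac
  } else {
    dn <- sens_counts(kind, params, sched, eval_times, param_name,
                      -delta_frac)
    num <- (up$count - dn$count) / base_counts$count
    denom <- 2 * delta_frac
  }
  out <- tibble::tibble(
    parameter = param_name,
    state = base_counts$state,
    time_day = base_counts$time_day,
    S_t = ifelse(base_counts$count > 0, num / denom, NA_real_)
  )
  dplyr::filter(out, as.character(.data$state) %in% states)
}

#' @rdname temporal_sensitivity
#' @export
local_sensitivity <- function(kind, params = default_params(kind),
                              param_name, sched = exchange_schedule(),
                              delta_frac = 0.01,
                              eval_times = c(0.5, 1, 2, 4, 7, 9),
                              states = hsc_states(kind),
                              side = c("forward", "central"),
                              average = c("signed", "absolute")) {
  average <- match.arg(average)
  tt <- temporal_sensitivity(kind, params, param_name, sched, delta_frac,
                             eval_times, states, side)
  if (anyNA(tt$S_t)) {
    bad <- unique(tt$time_day[is.na(tt$S_t)])
    rlang::warn(paste0(
      "baseline count is zero at t = ", paste(bad, collapse = ", "),
      " days for `", param_name, "`; those times are excluded"
    ))
  }
  agg <- if (average == "signed") function(x) mean(x) else
    function(x) mean(abs(x))
  dplyr::summarise(
    dplyr::group_by(tt, .data$parameter, .data$state),
    S = agg(.data$S_t[!is.na(.data$S_t)]),
    n_times = sum(!is.na(.data$S_t)),
    .groups = "drop"
  )
}

# simulate with param_name scaled by (1 + frac) and sample state counts
sens_counts <- function(kind, params, sched, eval_times, param_name, frac) {
  params <- validate_params(params)
  init <- params$init
  if (grepl("^init_", param_name)) {
    st <- sub("^init_", "", param_name)
    if (!st %in% hsc_states(kind)) {
      rlang::abort(paste0("unknown initial-population parameter `",
                          param_name, "`"))
    }
    if (init[[st]] <= 0 && frac != 0) {
      rlang::abort("cannot perturb a zero initial population")
    }
    init[[st]] <- init[[st]] * (1 + frac)
    p <- params
  } else {
    if (!param_name %in% names(params$values)) {
      rlang::abort(paste0("unknown parameter `", param_name, "`"))
    }
    if (params$values[[param_name]] <= 0 && frac != 0) {
      rlang::abort(paste0("`", param_name,
                          "` has a zero base value; nothing to perturb"))
    }
    p <- update_params(
      params,
      stats::setNames(params$values[[param_name]] * (1 + frac), param_name)
    )
  }
  traj <- simulate_culture(kind, p, sched, init = init,
                           sample_times = eval_times)
  sample_trajectory(traj, eval_times)
}

#' State-by-parameter sensitivity matrix
#'
#' Applies [local_sensitivity()] to every perturbable parameter, producing
#' the states-by-parameters matrix of time-averaged sensitivities. Entries
#' with `|S| > 1` — the output moves by more than 1% for a 1% parameter
#' change — are flagged as high impact.
#'
#' @inheritParams temporal_sensitivity
#' @param average Passed to [local_sensitivity()].
#' @param parameters Parameter names to scan; default all perturbable ones.
#' @return An `hsc_sensitivity` tibble `(state, parameter, S, flagged)` with
#'   the run configuration in attributes.
#' @examples
#' \donttest{
#' sm <- sensitivity_matrix("three_state")
#' dplyr::count(sm, state, flagged)
#' }
#' @export
sensitivity_matrix <- function(kind, params = default_params(kind),
                               sched = exchange_schedule(),
                               delta_frac = 0.01,
                               eval_times = c(0.5, 1, 2, 4, 7, 9),
                               side = c("forward", "central"),
                               average = c("signed", "absolute"),
                               parameters = NULL) {
  kind <- match_kind(kind)
  params <- validate_params(params)
  side <- match.arg(side); average <- match.arg(average)
  if (is.null(parameters)) parameters <- perturbable_params(params)
  out <- purrr::map_dfr(parameters, function(pn) {
    local_sensitivity(kind, params, pn, sched, delta_frac, eval_times,
                      side = side, average = average)
  })
  out <- dplyr::mutate(
    out,
    state = factor(as.character(.data$state), levels = hsc_states(kind)),
    flagged = abs(.data$S) > 1
  )
  out <- dplyr::select(out, "state", "parameter", "S", "flagged")
  out <- dplyr::arrange(out, .data$state, .data$parameter)
  attr(out, "kind") <- kind
  attr(out, "delta_frac") <- delta_frac
  attr(out, "eval_times") <- eval_times
  class(out) <- c("hsc_sensitivity", class(out))
  out
}

#' Write / read a sensitivity matrix as CSV
#'
#' Plain CSV with columns `state, parameter, S, flagged`; `read_sensitivity()`
#' restores the `hsc_sensitivity` class (the matrix round-trips exactly at
#' 15 significant digits).
#'
#' @param x An `hsc_sensitivity` tibble.
#' @param path Output CSV path.
#' @param kind Model variant of the stored matrix.
#' @return `write_sensitivity()` returns `path` invisibly.
#' @export
write_sensitivity <- function(x, path) {
  stopifnot(inherits(x, "hsc_sensitivity"))
  df <- as.data.frame(x)
  df$state <- as.character(df$state)
  utils::write.csv(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path, kind) {
  kind <- match_kind(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  out$state <- factor(out$state, levels = hsc_states(kind))
  out$flagged <- as.logical(out$flagged)
  attr(out, "kind") <- kind
  class(out) <- c("hsc_sensitivity", class(out))
  out
}

#' Heat-map view of a sensitivity matrix
#'
#' States on the vertical axis, parameters on the horizontal, fill mapped to
#' the signed sensitivity; high-impact cells (`|S| > 1`) are outlined.
#'
#' @param object An `hsc_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hsc_sensitivity <- function(object, ...) {
  df <- tibble::as_tibble(object)
  lim <- max(abs(df$S), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$state)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$S)) +
    ggplot2::geom_tile(
      data = dplyr::filter(df, .data$flagged),
      fill = NA, colour = "red", linewidth = 0.6
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-lim, lim)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "S") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
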