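#' Log-scale lack-of-fit between model and observed counts
#'
#' Cell numbers in these cultures span four orders of magnitude (hundreds of
#' LSK against ~6e5 Terminal cells), so residuals are taken on the log scale:
#' `r = log(model + delta) - log(observed + delta)` with `delta` = 1 cell,
#' summed as squares over every observed state and time with equal state
#' weights. With `weighting = "sem"` each residual is divided by the
#' observation's relative SEM (`sem / (count + delta)`), down-weighting noisy
#' points.
#'
#' @param params An `hsc_params` object.
#' @param observed Long-format observations: tibble with columns `time_day`,
#'   `state`, `count` and optionally `sem` (see [read_timeseries()]).
#' @param sched An [exchange_schedule()].
#' @param init Initial populations; default taken from `params`.
#' @param delta Log offset, cells.
#' @param weighting `"equal"` or `"sem"`.
#' @param grid_by Dense grid spacing passed to [simulate_culture()].
#' @return `timeseries_loss()` returns the scalar loss;
#'   `loss_decomposition()` returns a tibble of per-state loss contributions.
#' @examples
#' p <- default_params("three_state")
#' obs <- generate_observations("three_state", noise = noise_model("none"))
#' timeseries_loss(p, obs)
#' @export
timeseries_loss <- function(params, observed, sched = exchange_schedule(),
                            init = NULL, delta = 1,
                            weighting = c("equal", "sem"), grid_by = 0.25) {
  r <- loss_residuals(params, observed, sched, init, delta,
                      match.arg(weighting), grid_by)
  sum(r$residual^2)
}

#' @rdname timeseries_loss
#' @export
loss_decomposition <- function(params, observed, sched = exchange_schedule(),
                               init = NULL, delta = 1,
                               weighting = c("equal", "sem"),
                               grid_by = 0.25) {
  r <- loss_residuals(params, observed, sched, init, delta,
                      match.arg(weighting), grid_by)
  dplyr::summarise(dplyr::group_by(r, .data$state),
                   loss = sum(.data$residual^2), .groups = "drop")
}

loss_residuals <- function(params, observed, sched, init, delta, weighting,
                           grid_by) {
  stopifnot(inherits(params, "hsc_params"))
  observed <- validate_observations(observed, params$kind)
  if (nrow(observed) == 0) rlang::abort("`observed` has no rows")
  times <- sort(unique(observed$time_day))
  traj <- simulate_culture(params$kind, params, sched, init = init,
                           sample_times = times, grid_by = grid_by)
  model <- sample_trajectory(traj, times)
  joined <- dplyr::left_join(
    observed,
    dplyr::rename(model, model_count = "count"),
    by = c("time_day", "state")
  )
  res <- log(joined$model_count + delta) - log(joined$count + delta)
  if (weighting == "sem") {
    if (!"sem" %in% names(joined) || any(is.na(joined$sem))) {
      rlang::abort("`weighting = \"sem\"` requires a complete `sem` column")
    }
    rel <- pmax(joined$sem / (joined$count + delta), 1e-6)
    res <- res / rel
  }
  tibble::tibble(time_day = joined$time_day, state = joined$state,
                 residual = res)
}

validate_observations <- function(observed, kind) {
  need <- c("time_day", "state", "count")
  if (!all(need %in% names(observed))) {
    rlang::abort("observations need columns time_day, state, count")
  }
  states <- hsc_states(kind)
  obs_states <- unique(as.character(observed$state))
  bad <- setdiff(obs_states, states)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "observed states do not match the ", kind, " model: unknown ",
      paste(bad, collapse = ", ")
    ))
  }
  if (any(observed$count < 0) || any(observed$time_day < 0)) {
    rlang::abort("observed counts and times must be non-negative")
  }
  observed$state <- as.character(observed$state)
  observed
}

#' Fit kinetic parameters to observed counts
#'
#' Bounded least-squares estimation of a declared subset of parameters by
#' Levenberg--Marquardt on the log-scale residuals, with seeded multi-start
#' (Latin hypercube over the box, in log10 space). Parameters outside `free`
#' stay frozen at their `init_params` values. Six sampling times cannot
#' identify the full 30+-dimensional parameter set, so fits of more than
#' `max_free` parameters are refused unless `force = TRUE`.
#'
#' @param observed Long-format observations (see [timeseries_loss()]).
#' @param kind `"three_state"` or `"five_state"`.
#' @param init_params Starting `hsc_params`; also supplies frozen values.
#' @param free Character vector of parameter names to estimate (positive base
#'   values required). Empty means evaluate `init_params` only.
#' @param sched An [exchange_schedule()].
#' @param lower,upper Optional named bounds on the free parameters; default
#'   is a factor-of-10 box around `init_params`, capped at 1 for fraction
#'   maxima.
#' @param n_restarts Number of starts (>= 1); the first is `init_params`.
#' @param seed Integer seed controlling the restart draws.
#' @param max_free Refusal threshold for the size of `free`.
#' @param force Set `TRUE` to fit more than `max_free` parameters anyway.
#' @param weighting,delta,grid_by Passed to the loss.
#' @return An `hsc_fit` object; see [tidy.hsc_fit()] and [glance.hsc_fit()].
#' @export
fit_params <- function(observed, kind, init_params = default_params(kind),
                       free = character(), sched = exchange_schedule(),
                       lower = NULL, upper = NULL, n_restarts = 1, seed = 1,
                       max_free = 10, force = FALSE,
                       weighting = c("equal", "sem"), delta = 1,
                       grid_by = 0.25) {
  kind <- match_kind(kind)
  init_params <- validate_params(init_params)
  stopifnot(init_params$kind == kind, n_restarts >= 1)
  weighting <- match.arg(weighting)
  observed <- validate_observations(observed, kind)

  if (length(free) > max_free && !force) {
    rlang::abort(paste0(
      length(free), " free parameters exceed `max_free` = ", max_free,
      "; a handful of sampling times cannot identify that many. ",
      "Fit a sensitivity-guided subset, or pass `force = TRUE`."
    ))
  }
  bad <- setdiff(free, names(init_params$values))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown free parameter(s): ",
                        paste(bad, collapse = ", ")))
  }
  if (any(init_params$values[free] <= 0)) {
    rlang::abort("free parameters must have positive starting values")
  }

  init_loss <- timeseries_loss(init_params, observed, sched, delta = delta,
                               weighting = weighting, grid_by = grid_by)
  if (!is.finite(init_loss)) {
    rlang::abort(paste0(
      "loss is not finite at `init_params`; run validate_params() and check ",
      "the schedule/initial populations"
    ))
  }
  if (length(free) == 0) {
    return(new_hsc_fit(init_params, init_params, init_loss, observed, sched,
                       free, converged = TRUE, iterations = 0L,
                       n_restarts = 0L, lower = numeric(), upper = numeric(),
                       weighting = weighting, delta = delta,
                       grid_by = grid_by))
  }

  base <- init_params$values[free]
  frac <- grepl("^(f_max|q_max|j_max)", free)
  if (is.null(lower)) lower <- base / 10
  if (is.null(upper)) upper <- pmin(base * 10, ifelse(frac, 1, Inf))
  lower <- unlist(lower)[free]; upper <- unlist(upper)[free]
  if (any(is.na(lower)) || any(is.na(upper)) || any(lower <= 0) ||
      any(lower > base) || any(upper < base)) {
    rlang::abort("`lower`/`upper` must be positive and enclose the start")
  }

  # optimize in log10 space: parameters are positive and scale-heterogeneous
  llo <- log10(lower); lup <- log10(upper)
  resid_fun <- function(theta) {
    p <- update_params(init_params,
                       stats::setNames(10^theta, free))
    loss_residuals(p, observed, sched, init = NULL, delta, weighting,
                   grid_by)$residual
  }

  starts <- matrix(log10(base), nrow = 1)
  if (n_restarts > 1) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    hyper <- lhs::randomLHS(n_restarts - 1L, length(free))
    extra <- sweep(hyper, 2, lup - llo, "*")
    extra <- sweep(extra, 2, llo, "+")
    starts <- rbind(starts, extra)
  }

  best <- NULL
  iterations <- 0L
  for (k in seq_len(nrow(starts))) {
    fitk <- try(minpack.lm::nls.lm(
      par = pmin(pmax(starts[k, ], llo), lup),
      lower = llo, upper = lup, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(fitk, "try-error")) next
    iterations <- iterations + fitk$niter
    lossk <- sum(fitk$fvec^2)
    if (is.null(best) || lossk < best$loss) {
      best <- list(fit = fitk, loss = lossk)
    }
  }
  if (is.null(best)) rlang::abort("all optimization starts failed")

  # never worse than the start
  if (best$loss <= init_loss) {
    est <- stats::setNames(10^best$fit$par, free)
    final <- update_params(init_params, est)
    final_loss <- best$loss
    converged <- best$fit$info %in% 1:4
  } else {
    final <- init_params
    final_loss <- init_loss
    converged <- FALSE
  }
  new_hsc_fit(final, init_params, final_loss, observed, sched, free,
              converged = converged, iterations = iterations,
              n_restarts = nrow(starts), lower = lower, upper = upper,
              weighting = weighting, delta = delta, grid_by = grid_by)
}

new_hsc_fit <- function(params, init_params, loss, observed, sched, free,
                        converged, iterations, n_restarts, lower, upper,
                        weighting, delta, grid_by) {
  per_state <- loss_decomposition(params, observed, sched, delta = delta,
                                  weighting = weighting, grid_by = grid_by)
  at_bound <- character()
  if (length(free) > 0) {
    est <- params$values[free]
    tol <- 1e-6
    at_bound <- free[est <= lower * (1 + tol) | est >= upper * (1 - tol)]
  }
  structure(
    list(params = params, init_params = init_params, loss = loss,
         per_state_loss = per_state, free = free, lower = lower,
         upper = upper, at_bound = at_bound, converged = converged,
         iterations = iterations, n_restarts = n_restarts,
         n_obs = nrow(observed), weighting = weighting),
    class = "hsc_fit"
  )
}

#' @export
print.hsc_fit <- function(x, ...) {
  cat(sprintf(
    "<hsc_fit> %s; %d free parameter(s); loss = %.4g; %s\n",
    x$params$kind, length(x$free), x$loss,
    if (x$converged) "converged" else "not converged"
  ))
  if (length(x$free) > 0) print(tidy(x))
  invisible(x)
}

#' Tidy and summarize a parameter fit
#'
#' `tidy()` lists the free parameters with their starting values, estimates
#' and bound status; `glance()` gives the one-row fit summary.
#'
#' @param x An `hsc_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hsc_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$free,
    start = unname(x$init_params$values[x$free]),
    estimate = unname(x$params$values[x$free]),
    at_bound = x$free %in% x$at_bound
  )
}

#' @rdname tidy.hsc_fit
#' @export
glance.hsc_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$params$kind, loss = x$loss, n_free = length(x$free),
    n_obs = x$n_obs, converged = x$converged, iterations = x$iterations,
    n_restarts = x$n_restarts
  )
}
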