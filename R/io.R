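#' Read and write observed cell-count time series
#'
#' Long-format CSV with header `time_day, state, count` and optional
#' `sem, n_rep` columns. Counts and times must be non-negative and every
#' state label must belong to the declared model variant; violations are
#' reported with the offending row.
#'
#' @param path CSV path.
#' @param kind Model variant the series must match.
#' @param series Tibble as returned by [generate_observations()] or
#'   [read_timeseries()].
#' @return `read_timeseries()` returns a tibble `(time_day, state, count
#'   [, sem, n_rep])`; `write_timeseries()` returns `path` invisibly.
#' @examples
#' obs <- generate_observations("three_state", noise = noise_model("none"))
#' path <- tempfile(fileext = ".csv")
#' write_timeseries(obs, path)
#' read_timeseries(path, "three_state")
#' @export
read_timeseries <- function(path, kind) {
  kind <- match_kind(kind)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  df <- try(utils::read.csv(path, stringsAsFactors = FALSE), silent = TRUE)
  if (inherits(df, "try-error")) {
    rlang::abort(paste0("cannot parse CSV at ", path))
  }
  need <- c("time_day", "state", "count")
  if (!all(need %in% names(df))) {
    rlang::abort(paste0("CSV must have columns ",
                        paste(need, collapse = ", ")))
  }
  for (col in intersect(c("time_day", "count", "sem"), names(df))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      rlang::abort(sprintf("non-numeric `%s` at data row %d", col,
                           if (is.na(bad)) 1L else bad))
    }
  }
  states <- hsc_states(kind)
  bad_state <- which(!df$state %in% states)
  if (length(bad_state) > 0) {
    rlang::abort(sprintf(
      "state `%s` at data row %d is not a %s model state (expected %s)",
      df$state[bad_state[1]], bad_state[1], kind,
      paste(states, collapse = ", ")
    ))
  }
  bad_neg <- which(df$count < 0 | df$time_day < 0)
  if (length(bad_neg) > 0) {
    rlang::abort(sprintf("negative count or time at data row %d",
                         bad_neg[1]))
  }
  out <- tibble::as_tibble(df)
  out$state <- factor(out$state, levels = states)
  dplyr::arrange(out, .data$state, .data$time_day)
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(series, path) {
  need <- c("time_day", "state", "count")
  if (!all(need %in% names(series))) {
    rlang::abort(paste0("series must have columns ",
                        paste(need, collapse = ", ")))
  }
  df <- as.data.frame(series)
  df$state <- as.character(df$state)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                scientific = TRUE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as tidy CSV with a JSON sidecar
#'
#' Writes one row per grid time and state (`time_day, state, count`) plus the
#' environment columns repeated per row, and a `<path>.json` sidecar with the
#' run configuration (variant, schedule, initial populations) so the run can
#' be reproduced.
#'
#' @param traj An `hsc_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hsc_trajectory"))
  long <- tidy(traj)
  envc <- dplyr::select(tibble::as_tibble(traj),
                        dplyr::all_of(c("time_day", env_fields())))
  out <- dplyr::left_join(long, envc, by = "time_day")
  write_timeseries(out, path)
  sched <- attr(traj, "schedule")
  meta <- list(
    kind = attr(traj, "kind"),
    schedule = sched[c("frequency", "horizon", "scf_input", "gc_input",
                       "media_volume")],
    init = as.list(attr(traj, "init"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
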