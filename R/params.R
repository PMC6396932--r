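#' Kinetic parameter sets
#'
#' An `hsc_params` object holds the full kinetic parameter set of one model
#' variant as a named numeric vector, together with the initial populations
#' and the reference scales that nondimensionalize the feedback exponentials.
#'
#' `default_params()` loads the packaged calibrated defaults for a variant.
#' These defaults were calibrated against the population-scale anchors of the
#' culture the model describes: 5000 seeded LSK cells, Terminal expansion to a
#' peak near 6e5 cells by day 9 under 2-day media exchange, LSK numbers
#' cycling between roughly 1e2 and 2e3 with a biphasic minimum near day 4, and
#' a CMP compartment that spikes before day 1 but stays below ~300 cells.
#'
#' `hsc_params()` builds a parameter object from a named list/vector (all
#' fields required), and `validate_params()` enforces the invariants:
#' everything non-negative, fraction maxima (`f_max*`, `q_max*`, `j_max*`)
#' at most 1, and the state-indexed fields complete for the variant.
#'
#' @param kind `"three_state"` or `"five_state"`.
#' @param values Named numeric vector or list of parameter values.
#' @param init Named numeric vector of initial populations (cells), one entry
#'   per model state.
#' @param x An `hsc_params` object.
#' @return An object of class `hsc_params`.
#' @examples
#' p <- default_params("three_state")
#' p$values[["j_max_LSK"]]
#' @export
default_params <- function(kind) {
  kind <- match_kind(kind)
  path <- system.file("params", paste0(kind, ".yaml"), package = "hscdyn",
                      mustWork = TRUE)
  read_params(path)
}

#' @rdname default_params
#' @export
hsc_params <- function(kind, values, init) {
  kind <- match_kind(kind)
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    rlang::abort("all parameter values must be named")
  }
  init <- unlist(init)
  obj <- structure(
    list(kind = kind, values = values, init = init),
    class = "hsc_params"
  )
  validate_params(obj)
}

#' @rdname default_params
#' @export
validate_params <- function(x) {
  stopifnot(inherits(x, "hsc_params"))
  needed <- param_names(x$kind)
  missing <- setdiff(needed, names(x$values))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing parameter fields: ",
                        paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(x$values), needed)
  if (length(extra) > 0) {
    rlang::abort(paste0("unknown parameter fields: ",
                        paste(extra, collapse = ", ")))
  }
  vals <- x$values
  if (any(!is.finite(vals)) || any(vals < 0)) {
    bad <- names(vals)[!is.finite(vals) | vals < 0]
    rlang::abort(paste0("parameters must be finite and non-negative; bad: ",
                        paste(bad, collapse = ", ")))
  }
  frac <- grep("^(f_max|q_max|j_max)", names(vals), value = TRUE)
  if (any(vals[frac] > 1)) {
    bad <- frac[vals[frac] > 1]
    rlang::abort(paste0("fraction maxima must be <= 1; bad: ",
                        paste(bad, collapse = ", ")))
  }
  states <- hsc_states(x$kind)
  if (!setequal(names(x$init), states)) {
    rlang::abort(paste0("`init` must name exactly the states ",
                        paste(states, collapse = ", ")))
  }
  x$init <- x$init[states]
  if (any(!is.finite(x$init)) || any(x$init < 0)) {
    rlang::abort("initial populations must be finite and non-negative")
  }
  x
}

# Full parameter-name inventory per variant. The reference scales
# (c_hat, s_hat, t_hat) are structural and excluded from perturbation sets.
param_names <- function(kind) {
  kind <- match_kind(kind)
  if (kind == "three_state") {
    c(
      paste0("PR_max_", c("LSK", "CMP", "Terminal")),
      paste0("death_max_", c("LSK", "CMP", "Terminal")),
      paste0("d_", c("LSK", "CMP", "Terminal")),
      "f_max_LSK", "s_LSK", "f_max_CMP", "s_CMP",
      "q_max_LSK", "j_max_LSK",
      "DR_LSKtoCMP", "DR_LSKtoTerminal", "DR_CMPtoTerminal",
      paste0("m_Prog_", c("DiffS", "DiffI", "ProS", "ProI")),
      paste0("m_Term_", c("DiffS", "DiffI", "ProS", "ProI")),
      "K_SCF_consumption", "K_GC_consumption",
      "c_hat", "s_hat", "t_hat"
    )
  } else {
    st <- c("LT_HSC", "ST_HSC", "MPP", "CMP", "Terminal")
    c(
      paste0("PR_", st),
      paste0("death_max_", st),
      paste0("d_", st),
      c(rbind(paste0("f_max_", st[1:4]), paste0("s_", st[1:4]))),
      paste0("q_max_", c("LT_HSC", "ST_HSC", "MPP")),
      "j_max_ST_HSCtoTerminal", "j_max_MPPtoTerminal",
      "DR_LTtoST", "DR_STtoMPP", "DR_MPPtoCMP", "DR_CMPtoTerminal",
      "DR_STtoTerminal", "DR_MPPtoTerminal",
      paste0("c_Prog_", c("DiffS", "DiffI", "ProS", "ProI")),
      paste0("c_Term_", c("DiffS", "DiffI", "ProS", "ProI")),
      "K_SCF_consumption", "K_GC_consumption",
      "t_hat"
    )
  }
}

#' Perturbable parameters of a parameter set
#'
#' Parameters eligible for local sensitivity perturbation or fitting: every
#' kinetic field with a strictly positive base value. Reference scales and
#' zero-valued parameters (a 1% perturbation of zero is still zero) are
#' excluded.
#'
#' @param params An `hsc_params` object.
#' @return Character vector of parameter names.
#' @export
perturbable_params <- function(params) {
  stopifnot(inherits(params, "hsc_params"))
  structural <- c("c_hat", "s_hat", "t_hat")
  nm <- setdiff(names(params$values), structural)
  nm[params$values[nm] > 0]
}

#' @export
print.hsc_params <- function(x, ...) {
  cat("<hsc_params> variant:", x$kind, "\n")
  cat("  states:", paste(hsc_states(x$kind), collapse = ", "), "\n")
  cat("  init  :", paste(sprintf("%s=%g", names(x$init), x$init),
                         collapse = ", "), "\n")
  cat("  ", length(x$values), "parameters; see tidy() for values\n")
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x An `hsc_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @importFrom generics tidy
#' @export
tidy.hsc_params <- function(x, ...) {
  tibble::tibble(parameter = names(x$values), value = unname(x$values))
}

#' Read / write parameter configuration files
#'
#' Parameter sets are stored as YAML documents with three blocks: `kind`,
#' `init` (initial populations, cells) and `params` (all kinetic fields by
#' name). Files are validated on read.
#'
#' @param path File path.
#' @param params An `hsc_params` object.
#' @return `read_params()` returns an `hsc_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such config file: ", path))
  doc <- yaml::read_yaml(path)
  for (field in c("kind", "init", "params")) {
    if (is.null(doc[[field]])) {
      rlang::abort(paste0("config file lacks required field `", field, "`"))
    }
  }
  hsc_params(doc$kind, unlist(doc$params), unlist(doc$init))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "hsc_params"))
  doc <- list(
    kind = params$kind,
    init = as.list(params$init),
    params = as.list(params$values)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

# replace named entries, preserving validation
update_params <- function(params, replacements) {
  vals <- params$values
  bad <- setdiff(names(replacements), names(vals))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  }
  vals[names(replacements)] <- unlist(replacements)
  hsc_params(params$kind, vals, params$init)
}

#' Remove the direct-to-Terminal jump from a parameter set
#'
#' Returns a copy of `params` with every `j_max*` field set to 0, leaving all
#' other parameters untouched. This is the ablated model used to test whether
#' the direct progenitor-to-Terminal transition is required to reproduce the
#' observed kinetics.
#'
#' @param params An `hsc_params` object.
#' @return An `hsc_params` with all jump maxima zeroed.
#' @examples
#' ablate_jump(default_params("three_state"))$values[["j_max_LSK"]]
#' @export
ablate_jump <- function(params) {
  stopifnot(inherits(params, "hsc_params"))
  jm <- grep("^j_max", names(params$values), value = TRUE)
  repl <- stats::setNames(rep(0, length(jm)), jm)
  update_params(params, repl)
}
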