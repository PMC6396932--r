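#' Model variants of the differentiation hierarchy
#'
#' Two nested hierarchies are supported. The 3-state model tracks the bulk
#' early-progenitor gate (LSK), the common myeloid progenitor (CMP) and a
#' single pooled mature compartment (Terminal). The 5-state model resolves the
#' LSK gate into long-term HSC (LT-HSC), short-term HSC (ST-HSC) and
#' multipotent progenitors (MPP), keeping CMP and Terminal.
#'
#' @param kind Character scalar, `"three_state"` or `"five_state"`.
#' @return `hsc_states()` returns the ordered character vector of state names;
#'   `hsc_kinds()` returns the valid `kind` strings.
#' @examples
#' hsc_states("three_state")
#' hsc_states("five_state")
#' @export
hsc_states <- function(kind) {
  kind <- match_kind(kind)
  switch(kind,
    three_state = c("LSK", "CMP", "Terminal"),
    five_state  = c("LT_HSC", "ST_HSC", "MPP", "CMP", "Terminal")
  )
}

#' @rdname hsc_states
#' @export
hsc_kinds <- function() c("three_state", "five_state")

match_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% hsc_kinds()) {
    rlang::abort(paste0(
      "`kind` must be one of ",
      paste0('"', hsc_kinds(), '"', collapse = ", "), "."
    ))
  }
  kind
}

# environment compartments tracked alongside the populations in the ODE state
env_fields <- function() {
  c("scf_conc", "gc_conc", "pool_DiffS", "pool_DiffI", "pool_ProS", "pool_ProI")
}

#' Culture environment snapshot
#'
#' Bundles the soluble-compartment state of a well: stem cell factor (SCF)
#' concentration, the nutrient/glucose stock (GC), the constant media volume,
#' and the four pools of cell-secreted biomolecules (amounts in the well):
#' differentiation stimulators/inhibitors (DiffS/DiffI) and proliferation
#' stimulators/inhibitors (ProS/ProI).
#'
#' @param scf_conc SCF concentration, ng/mL.
#' @param gc_conc Nutrient (glucose) concentration, mM.
#' @param media_volume Well volume, uL; constant over a simulation.
#' @param pool_DiffS,pool_DiffI,pool_ProS,pool_ProI Secreted pool amounts, ng.
#' @return A one-row tibble of class `hsc_environment`.
#' @examples
#' culture_environment()
#' @export
culture_environment <- function(scf_conc = 100, gc_conc = 10,
                                media_volume = 300,
                                pool_DiffS = 0, pool_DiffI = 0,
                                pool_ProS = 0, pool_ProI = 0) {
  vals <- c(scf_conc = scf_conc, gc_conc = gc_conc,
            pool_DiffS = pool_DiffS, pool_DiffI = pool_DiffI,
            pool_ProS = pool_ProS, pool_ProI = pool_ProI)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rlang::abort("culture environment fields must be finite and non-negative")
  }
  if (!is.finite(media_volume) || media_volume <= 0) {
    rlang::abort("`media_volume` must be a positive volume in uL")
  }
  out <- tibble::tibble(
    scf_conc = scf_conc, gc_conc = gc_conc, media_volume = media_volume,
    pool_DiffS = pool_DiffS, pool_DiffI = pool_DiffI,
    pool_ProS = pool_ProS, pool_ProI = pool_ProI
  )
  class(out) <- c("hsc_environment", class(out))
  out
}
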