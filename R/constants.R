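#' Physical constants and reference values used throughout the package
#'
#' Returns the default constants of the manikin data reduction: the nude
#' (air-layer) insulation `ia` and air-layer evaporative resistance `rea`
#' measured on the bare / textile-skin manikin, the Lewis relation `lewis`
#' linking thermal and evaporative transfer, the clo conversion factor
#' `clo_si` (1 clo = 0.155 m2K/W), the default relative humidity at the
#' wetted textile skin `skin_rh`, and the floor `heat_loss_floor` applied to
#' per-zone mean heat loss before any division (near-zero or slightly
#' negative zone fluxes occur under heavy, impermeable layering).
#'
#' @param ... named overrides for any of the defaults.
#' @return A named list of constants.
#' @examples
#' maniclo_constants()$clo_si
#' maniclo_constants(rea = 7.5)$rea
#' @export
maniclo_constants <- function(...) {
  defaults <- list(
    ia = 0.099,             # m2K/W, nude manikin air-layer insulation
    rea = 8.0,              # m2Pa/W, air-layer evaporative resistance (textile skin)
    lewis = 16.5e-3,        # K/Pa, Lewis relation
    clo_si = 0.155,         # m2K/W per clo
    skin_rh = 96,           # %, relative humidity at the wetted textile skin
    heat_loss_floor = 0.01  # W, floor on per-zone mean heat loss
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- names(overrides)[!vapply(overrides, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad) > 0L) {
    stop("constants must be positive scalars: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, overrides)
}
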