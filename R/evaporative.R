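# Wet-mode (isothermal, sweating textile skin) reduction: vapour pressures,
# skin-temperature correction, zone and whole-body evaporative resistance,
# clothing evaporative resistance and permeability indices.

#' Water vapour pressure
#'
#' Saturation-scaled vapour pressure p = exp(18.956 - 4030/(T + 235)) * RH,
#' with RH in percent and the result in pascals (the exponential term alone
#' is in hPa; multiplying by RH in % carries the factor 100 to Pa). At
#' 34 degC and 100% RH this gives about 5322 Pa, matching standard
#' psychrometric saturation pressure.
#'
#' @param temperature temperature (degC), above -235.
#' @param relative_humidity relative humidity (%), in \[0, 100\].
#' @return Vapour pressure (Pa). Vectorised.
#' @examples
#' vapour_pressure(34, 100)
#' @export
vapour_pressure <- function(temperature, relative_humidity) {
  if (any(relative_humidity < 0 | relative_humidity > 100)) {
    stop("relative_humidity must be in [0, 100] %", call. = FALSE)
  }
  stopifnot(all(temperature > -235))
  exp(18.956 - 4030 / (temperature + 235)) * relative_humidity
}

#' Flux correction of the wetted textile-skin temperature
#'
#' Evaporation cools the wetted textile skin below the controlled surface
#' set-point; the skin temperature is estimated as
#' T_sk,i = T_s,i - 0.0132 * Q_i with Q_i the zone heat flux in W/m2.
#'
#' @param surface_temp controlled surface temperature (degC).
#' @param heat_flux zone heat flux (W/m2).
#' @return Corrected textile-skin temperature (degC). Vectorised.
#' @examples
#' corrected_skin_temperature(34, 100)
#' @export
corrected_skin_temperature <- function(surface_temp, heat_flux) {
  surface_temp - 0.0132 * heat_flux
}

#' Evaporative resistance of a single zone
#'
#' R_et,i = (p_sk,i - p_a) * A_i / H_i.
#'
#' @param skin_vp vapour pressure at the zone's textile skin (Pa).
#' @param air_vp ambient vapour pressure (Pa); must be below `skin_vp`.
#' @param area zone area (m2).
#' @param heat_loss zone evaporative heat loss (W), positive after flooring.
#' @param zone optional zone names for error messages.
#' @return Zone evaporative resistance (m2Pa/W). Vectorised.
#' @export
zone_evap_resistance <- function(skin_vp, air_vp, area, heat_loss, zone = NULL) {
  grad <- skin_vp - air_vp
  if (any(grad <= 0)) {
    bad <- if (is.null(zone)) which(grad <= 0) else zone[grad <= 0]
    stop("non-positive vapour-pressure gradient for zone(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(heat_loss <= 0)) {
    bad <- if (is.null(zone)) which(heat_loss <= 0) else zone[heat_loss <= 0]
    stop("non-positive heat loss for zone(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grad * area / heat_loss
}

#' Whole-body evaporative resistance from steady-state zone means
#'
#' Under isothermal conditions (air, surface and skin temperature nominally
#' equal) the only heat-exchange pathway is evaporation, so measured zone
#' heat losses are taken as evaporative losses. Two whole-body values are
#' reported: `ret_raw`, driven by the vapour pressure at the uncorrected
#' surface temperature, and `ret`, driven by the pressure at the
#' flux-corrected textile-skin temperature ([corrected_skin_temperature()]).
#' With positive flux the correction lowers the driving pressure, so
#' `ret <= ret_raw`.
#'
#' @param steady a `manikin_steady` from [average_window()] of a wet trial,
#'   or a zone-means tibble (then `geometry`, `environment`, `skin_rh` are
#'   required).
#' @param geometry,environment,skin_rh used when `steady` is a bare tibble.
#' @param isothermal_warn_tol,isothermal_fail_tol allowed |mean surface
#'   temperature - air temperature| (degC) before warning / failure.
#' @param heat_loss_floor floor (W) on per-zone mean heat loss.
#' @return An `evap_result`: list with `ret_raw`, `ret`, `zone_ret`,
#'   `heat_flux` (whole-body W/m2), `zone_heat_flux`, `evap_zone_losses`,
#'   `skin_state` (zone and mean corrected skin temperatures, skin RH),
#'   `isothermal_deviation`. `recl`, `im`, `im_cl` are filled by
#'   [compute_evap()] when f_cl and I_T are known.
#' @export
whole_body_evap_resistance <- function(steady, geometry = NULL,
                                       environment = NULL, skin_rh = NULL,
                                       isothermal_warn_tol = 0.5,
                                       isothermal_fail_tol = 3,
                                       heat_loss_floor = maniclo_constants()$heat_loss_floor) {
  if (inherits(steady, "manikin_steady")) {
    geometry <- steady$geometry
    environment <- steady$environment
    if (is.null(skin_rh)) skin_rh <- steady$skin_rh
    zm <- steady$zone_means
  } else {
    zm <- steady
  }
  if (is.null(skin_rh)) skin_rh <- maniclo_constants()$skin_rh
  idx <- match(geometry$zone, zm$zone)
  temps <- zm$surface_temp_C[idx]
  losses <- floor_heat_loss(zm$heat_loss_W[idx], heat_loss_floor)
  if (all(zm$heat_loss_W[idx] <= 0)) {
    stop("zero heat flux everywhere: evaporative resistance undefined",
         call. = FALSE)
  }
  areas <- geometry$area
  total_area <- attr(geometry, "total_area")

  mean_ts <- sum(temps * areas) / total_area
  iso_dev <- abs(mean_ts - environment$air_temperature)
  if (iso_dev > isothermal_fail_tol) {
    stop(sprintf("isothermal assumption violated: |Ts - Ta| = %.2f degC > %g degC",
                 iso_dev, isothermal_fail_tol), call. = FALSE)
  }
  if (iso_dev > isothermal_warn_tol) {
    warning(sprintf("isothermal deviation %.2f degC exceeds %g degC",
                    iso_dev, isothermal_warn_tol), call. = FALSE)
  }

  zone_flux <- losses / areas
  tsk <- corrected_skin_temperature(temps, zone_flux)
  mean_tsk <- sum(tsk * areas) / total_area

  p_s <- vapour_pressure(mean_ts, skin_rh)
  p_sk <- vapour_pressure(mean_tsk, skin_rh)
  p_sk_zone <- vapour_pressure(tsk, skin_rh)
  p_a <- vapour_pressure(environment$air_temperature,
                         environment$relative_humidity)
  if (p_s <= p_a || p_sk <= p_a) {
    stop("non-positive whole-body vapour-pressure gradient", call. = FALSE)
  }

  flux <- sum(losses) / total_area
  ret_raw <- (p_s - p_a) * total_area / sum(losses)
  ret <- (p_sk - p_a) * total_area / sum(losses)
  zone_ret <- zone_evap_resistance(p_sk_zone, p_a, areas, losses,
                                   zone = geometry$zone)

  structure(
    list(
      ret_raw = ret_raw, ret = ret,
      recl = NULL, rea = NULL, im = NULL, im_cl = NULL,
      zone_ret = stats::setNames(zone_ret, geometry$zone),
      heat_flux = flux,
      zone_heat_flux = stats::setNames(zone_flux, geometry$zone),
      evap_zone_losses = stats::setNames(losses, geometry$zone),
      skin_state = list(
        zone_skin_temps = stats::setNames(tsk, geometry$zone),
        mean_skin_temp = mean_tsk, mean_surface_temp = mean_ts,
        skin_rh = skin_rh),
      isothermal_deviation = iso_dev
    ),
    class = "evap_result"
  )
}

#' Clothing evaporative resistance
#'
#' R_ecl = R_et - R_ea / f_cl: the clothing-only evaporative resistance
#' after removing the boundary air layer, mirroring the basic-insulation
#' decomposition.
#'
#' @param ret total evaporative resistance (m2Pa/W).
#' @param rea air-layer evaporative resistance (m2Pa/W), measured with the
#'   bare textile skin.
#' @param fcl clothing area factor (>= 1).
#' @return Clothing evaporative resistance (m2Pa/W). Vectorised; a negative
#'   result triggers a warning.
#' @examples
#' clothing_evap_resistance(18.7, 8.0, 1.19)
#' @export
clothing_evap_resistance <- function(ret, rea = maniclo_constants()$rea, fcl) {
  if (any(fcl < 1)) stop("fcl must be >= 1", call. = FALSE)
  out <- ret - rea / fcl
  if (any(out < 0)) {
    warning("negative clothing evaporative resistance for ", sum(out < 0),
            " value(s); reported as-is", call. = FALSE)
  }
  out
}

#' Moisture permeability indices
#'
#' i_m = I_T / (R_et * L) compares dry and evaporative transfer through the
#' full clothing-plus-air system; i_m,cl = I_cl / (R_ecl * L) is the
#' clothing-only analogue. L is the Lewis relation (16.5e-3 K/Pa).
#'
#' @param it total insulation I_T (m2K/W).
#' @param ret total evaporative resistance R_et (m2Pa/W), positive.
#' @param lewis Lewis relation (K/Pa).
#' @return Dimensionless index. Vectorised.
#' @examples
#' permeability_index(0.187, 18.7)
#' @export
permeability_index <- function(it, ret, lewis = maniclo_constants()$lewis) {
  stopifnot(all(ret > 0), all(lewis > 0))
  it / (ret * lewis)
}

#' @rdname permeability_index
#' @param icl basic insulation I_cl (m2K/W).
#' @param recl clothing evaporative resistance R_ecl (m2Pa/W), positive.
#' @export
clothing_permeability_index <- function(icl, recl,
                                        lewis = maniclo_constants()$lewis) {
  stopifnot(all(recl > 0), all(lewis > 0))
  icl / (recl * lewis)
}

#' Full wet-trial evaporative reduction
#'
#' Runs the wet pipeline on a trial: steady-state detection, window
#' averaging, whole-body raw and corrected evaporative resistance, and,
#' when a clothing area factor (and total insulation) is supplied, the
#' clothing evaporative resistance and permeability indices.
#'
#' @param trial a wet [manikin_trial()].
#' @param fcl clothing area factor; `NULL` skips `recl`/`im_cl`.
#' @param rea air-layer evaporative resistance (m2Pa/W).
#' @param it total dry insulation of the same configuration (m2K/W);
#'   `NULL` skips the permeability indices.
#' @param icl basic insulation (m2K/W) for `im_cl`; defaults to
#'   Eq.-style recomputation from `it`, `ia`, `fcl` when those are given.
#' @param ia air-layer insulation (m2K/W), used only for the `icl` default.
#' @param window optional precomputed window.
#' @param min_duration,slope_tolerance,cv_tolerance steady-state criteria.
#' @param ... passed to [whole_body_evap_resistance()].
#' @return An `evap_result` (see [whole_body_evap_resistance()]) with
#'   `recl`, `rea`, `im`, `im_cl` filled where the inputs allow.
#' @export
compute_evap <- function(trial, fcl = NULL, rea = maniclo_constants()$rea,
                         it = NULL, icl = NULL, ia = maniclo_constants()$ia,
                         window = NULL, min_duration = 600,
                         slope_tolerance = 0.005, cv_tolerance = 0.02, ...) {
  stopifnot(inherits(trial, "manikin_trial"))
  if (trial$mode != "wet") stop("compute_evap needs a wet trial", call. = FALSE)
  if (is.null(window)) {
    window <- detect_steady_state(trial, min_duration, slope_tolerance,
                                  cv_tolerance)
  }
  steady <- average_window(trial, window)
  res <- whole_body_evap_resistance(steady, ...)
  res$rea <- rea
  if (!is.null(fcl)) res$recl <- clothing_evap_resistance(res$ret, rea, fcl)
  if (!is.null(it)) {
    res$im <- permeability_index(it, res$ret)
    if (is.null(icl) && !is.null(fcl)) icl <- basic_insulation(it, ia, fcl)
    if (!is.null(icl) && !is.null(res$recl)) {
      res$im_cl <- clothing_permeability_index(icl, res$recl)
    }
  }
  res$window <- window
  res
}

#' @export
print.evap_result <- function(x, ...) {
  cat(sprintf("<evap_result> Ret,raw=%.2f  Ret=%.2f m2Pa/W  (Q=%.1f W/m2)",
              x$ret_raw, x$ret, x$heat_flux))
  if (!is.null(x$recl)) cat(sprintf("  Recl=%.2f", x$recl))
  if (!is.null(x$im)) cat(sprintf("  im=%.3f", x$im))
  cat("\n")
  invisible(x)
}
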