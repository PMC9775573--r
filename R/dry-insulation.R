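# Dry-mode reduction: steady-state zone means -> zone / group / whole-body
# total insulation, basic (intrinsic) insulation, clo conversion.

# Per-zone mean heat loss is floored before any division: under heavy,
# near-impermeable layering zone flux can drop to ~0 W (or slightly
# negative after sensor noise), which would blow up the per-zone quotient.
floor_heat_loss <- function(heat_loss, floor = maniclo_constants()$heat_loss_floor) {
  pmax(heat_loss, floor)
}

#' Total insulation of a single manikin zone
#'
#' I_T,i = (T_s,i - T_o) * A_i / H_c,i for zone i: the dry thermal
#' resistance between the zone surface and the environment.
#'
#' @param mean_temp zone mean surface temperature (degC).
#' @param operative_temp operative temperature (degC); must be below the
#'   surface temperature.
#' @param area zone area (m2).
#' @param mean_heat_loss zone mean dry heat loss (W), positive after
#'   flooring.
#' @param zone optional zone name for error messages.
#' @return Zone total insulation (m2K/W). Vectorised over zones.
#' @examples
#' zone_total_insulation(34, 10, 0.1, 12)  # 0.2 m2K/W
#' @export
zone_total_insulation <- function(mean_temp, operative_temp, area,
                                  mean_heat_loss, zone = NULL) {
  grad <- mean_temp - operative_temp
  if (any(grad <= 0)) {
    bad <- if (is.null(zone)) which(grad <= 0) else zone[grad <= 0]
    stop("non-positive temperature gradient for zone(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(mean_heat_loss <= 0)) {
    bad <- if (is.null(zone)) which(mean_heat_loss <= 0) else zone[mean_heat_loss <= 0]
    stop("non-positive heat loss for zone(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grad * area / mean_heat_loss
}

#' Zone contribution to whole-body insulation
#'
#' I_T,i,r = (A_i / A) * I_T,i; summing the contributions over all zones
#' gives the serial-method whole-body total.
#'
#' @param zone_insulation zone total insulation (m2K/W).
#' @param area zone area (m2).
#' @param total_area whole-body area (m2).
#' @return Contribution (m2K/W). Vectorised.
#' @export
zone_contribution <- function(zone_insulation, area, total_area) {
  stopifnot(all(area > 0), total_area > 0)
  (area / total_area) * zone_insulation
}

#' Total insulation of a zone group
#'
#' The group analogue of the whole-body global form: area-weighted mean
#' group surface temperature minus operative temperature, times group area,
#' divided by the summed group heat loss.
#'
#' @param steady a `manikin_steady` from [average_window()], or a tibble of
#'   zone means with columns `zone`, `surface_temp_C`, `heat_loss_W`.
#' @param group_zones character vector of member zone names (non-empty).
#' @param operative_temp operative temperature (degC); defaults to the
#'   steady object's environment.
#' @param geometry required when `steady` is a bare tibble.
#' @param heat_loss_floor floor (W) applied to the summed group heat loss.
#' @return Group total insulation (m2K/W).
#' @export
group_total_insulation <- function(steady, group_zones, operative_temp = NULL,
                                   geometry = NULL,
                                   heat_loss_floor = maniclo_constants()$heat_loss_floor) {
  zm <- if (inherits(steady, "manikin_steady")) steady$zone_means else steady
  if (is.null(geometry) && inherits(steady, "manikin_steady")) {
    geometry <- steady$geometry
  }
  if (is.null(operative_temp) && inherits(steady, "manikin_steady")) {
    operative_temp <- steady$environment$operative_temperature
  }
  if (length(group_zones) == 0L) stop("group must be non-empty", call. = FALSE)
  unknown <- setdiff(group_zones, geometry$zone)
  if (length(unknown) > 0L) {
    stop("group zone(s) not in geometry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(group_zones, zm$zone)
  areas <- geometry$area[match(group_zones, geometry$zone)]
  group_area <- sum(areas)
  mean_temp <- sum(zm$surface_temp_C[idx] * areas) / group_area
  heat <- max(sum(zm$heat_loss_W[idx]), heat_loss_floor)
  if (heat <= heat_loss_floor && sum(zm$heat_loss_W[idx]) <= 0) {
    stop("group heat loss non-positive after flooring", call. = FALSE)
  }
  (mean_temp - operative_temp) * group_area / heat
}

#' Whole-body total insulation
#'
#' Aggregates steady-state zone means into the whole-body total insulation
#' I_T by one of three conventions:
#' \describe{
#'   \item{global}{area-weighted mean surface temperature minus operative
#'     temperature, times whole-body area, divided by summed heat loss.
#'     Insensitive to zones whose flux drops to zero under heavy layering
#'     and the default throughout this package.}
#'   \item{serial}{sum of area-weighted zone contributions
#'     (area-weighted arithmetic mean of zone insulations).}
#'   \item{parallel}{area-weighted harmonic mean: A / sum(A_i / I_T,i),
#'     i.e. summation of zone conductances.}
#' }
#' Serial >= parallel always (AM-HM inequality); with a uniform surface
#' temperature global coincides with parallel.
#'
#' @inheritParams group_total_insulation
#' @param method `"global"` (default), `"serial"` or `"parallel"`.
#' @return Whole-body total insulation (m2K/W).
#' @examples
#' spec <- synthetic_spec(mode = "dry", seed = 7)
#' st <- average_window(generate_trial(spec), list(start_time = 3000, end_time = 3600))
#' whole_body_total_insulation(st)
#' @export
whole_body_total_insulation <- function(steady, method = c("global", "serial", "parallel"),
                                        operative_temp = NULL, geometry = NULL,
                                        heat_loss_floor = maniclo_constants()$heat_loss_floor) {
  method <- match.arg(method)
  zm <- if (inherits(steady, "manikin_steady")) steady$zone_means else steady
  if (is.null(geometry) && inherits(steady, "manikin_steady")) {
    geometry <- steady$geometry
  }
  if (is.null(operative_temp) && inherits(steady, "manikin_steady")) {
    operative_temp <- steady$environment$operative_temperature
  }
  missing_zones <- setdiff(geometry$zone, zm$zone)
  if (length(missing_zones) > 0L) {
    stop("missing zone mean(s): ", paste(missing_zones, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(geometry$zone, zm$zone)
  temps <- zm$surface_temp_C[idx]
  losses <- floor_heat_loss(zm$heat_loss_W[idx], heat_loss_floor)
  areas <- geometry$area
  total_area <- attr(geometry, "total_area")
  if (method == "global") {
    mean_temp <- sum(temps * areas) / total_area
    if (mean_temp <= operative_temp) {
      stop("non-positive whole-body temperature gradient", call. = FALSE)
    }
    return((mean_temp - operative_temp) * total_area / sum(losses))
  }
  zone_it <- zone_total_insulation(temps, operative_temp, areas, losses,
                                   zone = geometry$zone)
  if (method == "serial") {
    sum(zone_contribution(zone_it, areas, total_area))
  } else {
    total_area / sum(areas / zone_it)
  }
}

#' Basic (intrinsic) clothing insulation
#'
#' I_clu (item) or I_cl (ensemble) = I_T - I_a / f_cl: the clothing-only
#' insulation after removing the boundary air layer, scaled by the clothing
#' area factor. A negative result (possible for very thin items with
#' f_cl near 1 and last-digit rounding) is reported with a warning, not
#' clamped.
#'
#' @param total total insulation I_T (m2K/W).
#' @param air_layer nude air-layer insulation I_a (m2K/W).
#' @param fcl clothing area factor (>= 1, dimensionless).
#' @return Basic insulation (m2K/W). Vectorised.
#' @examples
#' basic_insulation(0.187, 0.099, 1.19)
#' @export
basic_insulation <- function(total, air_layer = maniclo_constants()$ia, fcl) {
  stopifnot(all(total > 0), all(air_layer > 0))
  if (any(fcl < 1)) stop("fcl must be >= 1", call. = FALSE)
  out <- total - air_layer / fcl
  if (any(out < 0)) {
    warning("negative basic insulation for ", sum(out < 0),
            " value(s); reported as-is", call. = FALSE)
  }
  out
}

#' Convert between m2K/W and clo
#'
#' 1 clo = 0.155 m2K/W.
#'
#' @param insulation insulation in m2K/W.
#' @param clo insulation in clo.
#' @return The converted value(s).
#' @examples
#' to_clo(0.155)
#' from_clo(1)
#' @export
to_clo <- function(insulation) insulation / maniclo_constants()$clo_si

#' @rdname to_clo
#' @export
from_clo <- function(clo) clo * maniclo_constants()$clo_si

#' Full dry-trial insulation reduction
#'
#' Runs the dry pipeline on a trial: steady-state detection, window
#' averaging, whole-body total insulation by the chosen method, and (when a
#' clothing area factor is supplied) basic insulation with the clo
#' conversion. Zone-level totals and contributions are always reported.
#'
#' @param trial a dry [manikin_trial()].
#' @param method aggregation method, see [whole_body_total_insulation()].
#' @param fcl clothing area factor; `NULL` skips basic insulation.
#' @param ia air-layer insulation (m2K/W).
#' @param window optional precomputed window; default runs
#'   [detect_steady_state()] with the arguments below.
#' @param min_duration,slope_tolerance,cv_tolerance steady-state criteria.
#' @return An `insulation_result`: list with `total_insulation`,
#'   `air_layer_insulation`, `clothing_area_factor`, `basic_insulation`,
#'   `basic_insulation_clo`, `method`, `zone_values`, `zone_contributions`,
#'   `window`, `n_samples`.
#' @export
compute_insulation <- function(trial, method = c("global", "serial", "parallel"),
                               fcl = NULL, ia = maniclo_constants()$ia,
                               window = NULL, min_duration = 600,
                               slope_tolerance = 0.005, cv_tolerance = 0.02) {
  method <- match.arg(method)
  stopifnot(inherits(trial, "manikin_trial"))
  if (trial$mode != "dry") stop("compute_insulation needs a dry trial",
                                call. = FALSE)
  if (is.null(window)) {
    window <- detect_steady_state(trial, min_duration, slope_tolerance,
                                  cv_tolerance)
  }
  steady <- average_window(trial, window)
  geo <- steady$geometry
  to_ <- steady$environment$operative_temperature
  losses <- floor_heat_loss(steady$zone_means$heat_loss_W)
  zone_it <- zone_total_insulation(steady$zone_means$surface_temp_C, to_,
                                   geo$area, losses, zone = geo$zone)
  total <- whole_body_total_insulation(steady, method = method)
  basic <- if (!is.null(fcl)) basic_insulation(total, ia, fcl) else NULL
  structure(
    list(
      total_insulation = total,
      air_layer_insulation = ia,
      clothing_area_factor = fcl,
      basic_insulation = basic,
      basic_insulation_clo = if (!is.null(basic)) to_clo(basic) else NULL,
      method = method,
      zone_values = stats::setNames(zone_it, geo$zone),
      zone_contributions = stats::setNames(
        zone_contribution(zone_it, geo$area, attr(geo, "total_area")),
        geo$zone),
      window = window,
      n_samples = steady$n_samples
    ),
    class = "insulation_result"
  )
}

#' @export
print.insulation_result <- function(x, ...) {
  cat(sprintf("<insulation_result> method=%s  I_T=%.4f m2K/W", x$method,
              x$total_insulation))
  if (!is.null(x$basic_insulation)) {
    cat(sprintf("  I_cl=%.4f m2K/W (%.2f clo, fcl=%.2f)",
                x$basic_insulation, x$basic_insulation_clo,
                x$clothing_area_factor))
  }
  cat("\n")
  invisible(x)
}
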