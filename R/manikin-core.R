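#' @importFrom tibble tibble as_tibble
#' @importFrom stats coef lm rnorm sd setNames
NULL

#' The 17 zone names of a segmented thermal manikin
#'
#' Zone naming follows the body segmentation of a male full-body manikin
#' with individually heated and controlled zones.
#'
#' @export
MANIKIN_ZONES <- c(
  "head", "chest", "back", "stomach", "buttocks",
  "left_upper_arm", "right_upper_arm", "left_lower_arm", "right_lower_arm",
  "left_hand", "right_hand", "left_thigh", "right_thigh",
  "left_calf", "right_calf", "left_foot", "right_foot"
)

#' Construct a manikin geometry
#'
#' A geometry is the ordered table of zone names and surface areas; the
#' whole-body area is their sum. All area-weighted reductions (mean surface
#' temperature, the global insulation method, zone contributions) read
#' areas from this object.
#'
#' @param zones character vector of unique zone names.
#' @param areas numeric vector of strictly positive zone areas (m2), one per
#'   zone.
#' @return An object of class `manikin_geometry`: a tibble with columns
#'   `zone` and `area`, with attribute `total_area`.
#' @examples
#' geo <- manikin_geometry(c("head", "torso"), c(0.11, 1.0))
#' attr(geo, "total_area")
#' @export
manikin_geometry <- function(zones, areas) {
  zones <- as.character(zones)
  if (anyDuplicated(zones)) stop("zone names must be unique", call. = FALSE)
  if (length(areas) != length(zones)) {
    stop("one area per zone required", call. = FALSE)
  }
  if (!is.numeric(areas) || any(!is.finite(areas)) || any(areas <= 0)) {
    stop("zone areas must be strictly positive", call. = FALSE)
  }
  geo <- tibble::tibble(zone = zones, area = as.numeric(areas))
  structure(geo, total_area = sum(geo$area),
            class = c("manikin_geometry", class(geo)))
}

#' Default 17-zone geometry
#'
#' A plausible area table for a male-shaped, 17-zone manikin, summing to
#' 1.77 m2. The areas are synthetic (chosen once as representative of this
#' class of instrument, not taken from any measured manikin) and are fully
#' configurable: supply your own table via [manikin_geometry()] for real
#' hardware.
#'
#' @param total_area optional whole-body area (m2); the default table is
#'   rescaled proportionally to match it.
#' @return A `manikin_geometry`.
#' @examples
#' geo <- default_geometry()
#' sum(geo$area)
#' @export
default_geometry <- function(total_area = NULL) {
  areas <- c(
    head = 0.11, chest = 0.15, back = 0.15, stomach = 0.12, buttocks = 0.12,
    left_upper_arm = 0.08, right_upper_arm = 0.08,
    left_lower_arm = 0.065, right_lower_arm = 0.065,
    left_hand = 0.05, right_hand = 0.05,
    left_thigh = 0.17, right_thigh = 0.17,
    left_calf = 0.125, right_calf = 0.125,
    left_foot = 0.07, right_foot = 0.07
  )
  stopifnot(identical(names(areas), MANIKIN_ZONES))
  if (!is.null(total_area)) areas <- areas * total_area / sum(areas)
  manikin_geometry(names(areas), unname(areas))
}

#' Construct a trial environment
#'
#' Holds the chamber conditions of one manikin trial. The operative
#' temperature defaults to the mean of air and radiant temperature; in a
#' well-mixed chamber where the mean radiant temperature equals the air
#' temperature it equals both.
#'
#' @param air_temperature air temperature (degC).
#' @param relative_humidity relative humidity (%), in \[0, 100\].
#' @param air_velocity mean air velocity (m/s), non-negative.
#' @param radiant_temperature mean radiant temperature (degC); defaults to
#'   the air temperature.
#' @param operative_temperature override (degC); defaults to the air/radiant
#'   mean.
#' @return An object of class `manikin_environment` (named list).
#' @examples
#' env <- manikin_environment(20, relative_humidity = 50, air_velocity = 0.18)
#' env$operative_temperature
#' @export
manikin_environment <- function(air_temperature,
                                relative_humidity,
                                air_velocity,
                                radiant_temperature = air_temperature,
                                operative_temperature = NULL) {
  if (relative_humidity < 0 || relative_humidity > 100) {
    stop("relative_humidity must be in [0, 100] %", call. = FALSE)
  }
  if (air_velocity < 0) stop("air_velocity must be >= 0", call. = FALSE)
  if (is.null(operative_temperature)) {
    operative_temperature <- (air_temperature + radiant_temperature) / 2
  }
  structure(
    list(
      air_temperature = air_temperature,
      radiant_temperature = radiant_temperature,
      operative_temperature = operative_temperature,
      relative_humidity = relative_humidity,
      air_velocity = air_velocity
    ),
    class = "manikin_environment"
  )
}

#' Construct a manikin trial record
#'
#' A trial is the time series of per-zone surface temperatures and heat
#' losses recorded over one exposure, together with the geometry and the
#' chamber environment. Wet (sweating textile skin) trials additionally
#' carry the relative humidity at the skin.
#'
#' @param trial_id identifier.
#' @param mode `"dry"` or `"wet"`.
#' @param geometry a [manikin_geometry()].
#' @param environment a [manikin_environment()].
#' @param data data frame with columns `time_s`, `zone`, `surface_temp_C`,
#'   `heat_loss_W`; every timestamp must carry exactly one sample per zone
#'   and timestamps must be strictly increasing.
#' @param skin_rh relative humidity at the textile skin (%), wet mode only.
#' @return An object of class `manikin_trial`.
#' @export
manikin_trial <- function(trial_id, mode, geometry, environment, data,
                          skin_rh = NULL) {
  mode <- match.arg(mode, c("dry", "wet"))
  stopifnot(inherits(geometry, "manikin_geometry"),
            inherits(environment, "manikin_environment"))
  required <- c("time_s", "zone", "surface_temp_C", "heat_loss_W")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("trial data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data[required])
  times <- sort(unique(data$time_s))
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing",
                                  call. = FALSE)
  counts <- table(data$time_s, data$zone)
  if (nrow(data) != length(times) * nrow(geometry) ||
      !all(counts == 1L) ||
      !setequal(colnames(counts), geometry$zone)) {
    stop("every timestamp must have exactly one sample per geometry zone",
         call. = FALSE)
  }
  if (mode == "dry" && !is.null(skin_rh)) {
    stop("dry trials must not carry skin_rh", call. = FALSE)
  }
  if (mode == "wet") {
    if (is.null(skin_rh)) skin_rh <- maniclo_constants()$skin_rh
    if (skin_rh < 0 || skin_rh > 100) stop("skin_rh must be in [0, 100] %",
                                           call. = FALSE)
  }
  structure(
    list(trial_id = as.character(trial_id), mode = mode, geometry = geometry,
         environment = environment, data = data, timestamps = times,
         skin_rh = skin_rh),
    class = "manikin_trial"
  )
}

#' @export
print.manikin_trial <- function(x, ...) {
  cat(sprintf("<manikin_trial '%s'> mode=%s, %d zones, %d timestamps (%g-%g s)\n",
              x$trial_id, x$mode, nrow(x$geometry), length(x$timestamps),
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

# Whole-body series used by the steady-state detector: summed heat loss (W)
# and area-weighted mean surface temperature (degC), one value per timestamp.
whole_body_series <- function(trial) {
  geo <- trial$geometry
  w <- geo$area[match(trial$data$zone, geo$zone)] / attr(geo, "total_area")
  ts <- trial$timestamps
  idx <- match(trial$data$time_s, ts)
  heat <- as.numeric(rowsum(trial$data$heat_loss_W, idx))
  temp <- as.numeric(rowsum(trial$data$surface_temp_C * w, idx))
  tibble::tibble(time_s = ts, heat_loss_W = heat, mean_surface_temp_C = temp)
}

# slope (per minute) of a linear trend, and coefficient of variation,
# both relative to the window mean
trend_stats <- function(time_s, value) {
  m <- mean(value)
  slope <- if (length(value) > 2L) {
    unname(stats::coef(stats::lm(value ~ I(time_s / 60)))[2L])
  } else 0
  list(mean = m,
       rel_slope = if (m != 0) abs(slope) / abs(m) else abs(slope),
       cv = if (m != 0) stats::sd(value) / abs(m) else Inf)
}

#' Detect the latest steady-state window of a trial
#'
#' Scans candidate windows of length `min_duration`, starting from the end
#' of the trial and moving one sample earlier at a time, and returns the
#' latest window in which both the whole-body heat loss and the area-weighted
#' mean surface temperature are stable: absolute linear-trend slope at most
#' `slope_tolerance` (as a fraction of the window mean, per minute) and
#' coefficient of variation at most `cv_tolerance`.
#'
#' @param trial a [manikin_trial()].
#' @param min_duration window length (s); the conventional choice for dry
#'   trials is the last 10 min (600 s) of stable state.
#' @param slope_tolerance maximum |trend slope| / mean per minute.
#' @param cv_tolerance maximum coefficient of variation (sd/mean).
#' @return A `steady_window`: list with `start_time`, `end_time` (s).
#' @examples
#' spec <- synthetic_spec(mode = "dry", seed = 1)
#' detect_steady_state(generate_trial(spec))
#' @export
detect_steady_state <- function(trial, min_duration = 600,
                                slope_tolerance = 0.005,
                                cv_tolerance = 0.02) {
  stopifnot(inherits(trial, "manikin_trial"))
  if (min_duration <= 0 || slope_tolerance <= 0 || cv_tolerance <= 0) {
    stop("min_duration and tolerances must be positive", call. = FALSE)
  }
  series <- whole_body_series(trial)
  span <- max(series$time_s) - min(series$time_s)
  if (span < min_duration) {
    stop(sprintf("trial spans %g s, shorter than min_duration %g s",
                 span, min_duration), call. = FALSE)
  }
  ends <- rev(series$time_s[series$time_s >= min(series$time_s) + min_duration])
  worst <- NULL
  for (end in ends) {
    start <- end - min_duration
    in_win <- series$time_s >= start & series$time_s <= end
    hl <- trend_stats(series$time_s[in_win], series$heat_loss_W[in_win])
    tp <- trend_stats(series$time_s[in_win], series$mean_surface_temp_C[in_win])
    ok_slope <- hl$rel_slope <= slope_tolerance && tp$rel_slope <= slope_tolerance
    ok_cv <- hl$cv <= cv_tolerance && tp$cv <= cv_tolerance
    if (ok_slope && ok_cv) {
      return(structure(list(start_time = start, end_time = end),
                       class = "steady_window"))
    }
    if (is.null(worst)) {
      worst <- if (!ok_slope) {
        sprintf("trend slope %.3g/min exceeds tolerance %.3g/min",
                max(hl$rel_slope, tp$rel_slope), slope_tolerance)
      } else {
        sprintf("coefficient of variation %.3g exceeds tolerance %.3g",
                max(hl$cv, tp$cv), cv_tolerance)
      }
    }
  }
  stop("no steady state: ", worst, call. = FALSE)
}

#' Average a trial over a time window
#'
#' Arithmetic per-zone means of surface temperature and heat loss over all
#' samples whose timestamps fall in `[start_time, end_time]`, carrying
#' geometry, environment and mode forward for the downstream reductions.
#'
#' @param trial a [manikin_trial()].
#' @param window a `steady_window` from [detect_steady_state()], or any list
#'   with `start_time` and `end_time` in seconds.
#' @return An object of class `manikin_steady`: list with `zone_means`
#'   (tibble `zone`, `surface_temp_C`, `heat_loss_W`), `environment`,
#'   `geometry`, `mode`, `skin_rh`, `n_samples`, `window`.
#' @export
average_window <- function(trial, window) {
  stopifnot(inherits(trial, "manikin_trial"))
  if (window$end_time <= window$start_time) {
    stop("window must have positive duration", call. = FALSE)
  }
  keep <- trial$data$time_s >= window$start_time &
    trial$data$time_s <= window$end_time
  if (!any(keep)) stop("window contains no samples", call. = FALSE)
  sub <- trial$data[keep, ]
  zm <- tibble::tibble(
    zone = trial$geometry$zone,
    surface_temp_C = as.numeric(tapply(sub$surface_temp_C, sub$zone,
                                       mean)[trial$geometry$zone]),
    heat_loss_W = as.numeric(tapply(sub$heat_loss_W, sub$zone,
                                    mean)[trial$geometry$zone])
  )
  structure(
    list(zone_means = zm, environment = trial$environment,
         geometry = trial$geometry, mode = trial$mode,
         skin_rh = trial$skin_rh,
         n_samples = length(unique(sub$time_s)), window = window),
    class = "manikin_steady"
  )
}

#' Repeatability check between two replicate measurements
#'
#' Replicate manikin runs of the same configuration are accepted when their
#' relative difference, |a - b| divided by the mean of the two, does not
#' exceed the threshold (default 4%); above it the measuring settings
#' should be checked and the test repeated.
#'
#' @param value_a,value_b the two replicate results (any common positive
#'   scale, e.g. m2K/W).
#' @param threshold_fraction acceptance threshold on the relative difference
#'   (default 0.04); equality passes.
#' @return List with `relative_difference` and logical `pass`.
#' @examples
#' repeatability_check(0.100, 0.103)
#' @export
repeatability_check <- function(value_a, value_b, threshold_fraction = 0.04) {
  if (!is.numeric(value_a) || !is.numeric(value_b) ||
      value_a <= 0 || value_b <= 0) {
    stop("both values must be positive", call. = FALSE)
  }
  rel <- abs(value_a - value_b) / mean(c(value_a, value_b))
  list(relative_difference = rel, pass = rel <= threshold_fraction)
}

#' Area-weighted mean surface temperature
#'
#' @param zone_temps named numeric vector of per-zone temperatures (degC),
#'   or the `zone_means` tibble of [average_window()].
#' @param geometry a [manikin_geometry()].
#' @return Mean surface temperature (degC), weighted by zone area.
#' @export
mean_surface_temperature <- function(zone_temps, geometry) {
  if (is.data.frame(zone_temps)) {
    zone_temps <- stats::setNames(zone_temps$surface_temp_C, zone_temps$zone)
  }
  missing_zones <- setdiff(geometry$zone, names(zone_temps))
  if (length(missing_zones) > 0L) {
    stop("missing temperature for zone(s): ",
         paste(missing_zones, collapse = ", "), call. = FALSE)
  }
  tvec <- zone_temps[geometry$zone]
  sum(tvec * geometry$area) / attr(geometry, "total_area")
}
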