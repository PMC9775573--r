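# Forward simulator of dry and wet manikin trials with known ground truth.
# Dry steady flux inverts the zone-insulation relation; wet steady flux
# solves the skin-temperature / flux fixed point, since evaporative cooling
# of the textile skin lowers the driving vapour pressure, which feeds back
# into the flux.

#' Specify a synthetic manikin trial
#'
#' Defines the ground truth and measurement model of one simulated trial:
#' surface set-point control at 34 degC, per-zone true insulation (dry) or
#' true evaporative resistance (wet), exponential warm-up of the zone heat
#' flux toward its steady value, and i.i.d. Gaussian sensor noise on
#' temperatures and fluxes. Defaults emulate the measurement conditions the
#' reductions assume: 10-s sampling, 0.18 m/s air at 20 degC / 50% RH for
#' dry trials, isothermal 34 degC / 40% RH / 0.40 m/s for wet trials.
#'
#' @param mode `"dry"` or `"wet"`.
#' @param geometry a [manikin_geometry()]; default [default_geometry()].
#' @param true_zone_insulation per-zone true total insulation (m2K/W): a
#'   scalar (recycled) or a vector named by zone. Dry mode only.
#' @param true_zone_evap_resistance per-zone true evaporative resistance
#'   (m2Pa/W), scalar or named vector. Wet mode only.
#' @param environment a [manikin_environment()]; mode-specific default.
#' @param setpoint controlled surface temperature (degC).
#' @param skin_rh relative humidity at the wetted skin (%), wet mode.
#' @param noise_sd_temp sd of surface-temperature noise (degC).
#' @param noise_sd_flux_fraction sd of flux noise as a fraction of the
#'   zone's steady flux.
#' @param duration trial length (s).
#' @param sample_interval sampling interval (s).
#' @param warmup_time_constant time constant of the exponential approach to
#'   steady flux (s); 0 starts at steady state.
#' @param seed integer seed making the generated trial reproducible.
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(mode = "dry", true_zone_insulation = 0.35, seed = 1)
#' @export
synthetic_spec <- function(mode = c("dry", "wet"),
                           geometry = default_geometry(),
                           true_zone_insulation = 0.187,
                           true_zone_evap_resistance = 18.7,
                           environment = NULL,
                           setpoint = 34, skin_rh = 96,
                           noise_sd_temp = 0.05,
                           noise_sd_flux_fraction = 0.02,
                           duration = 3600, sample_interval = 10,
                           warmup_time_constant = 300, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(environment)) {
    environment <- if (mode == "dry") {
      manikin_environment(20, relative_humidity = 50, air_velocity = 0.18)
    } else {
      manikin_environment(34, relative_humidity = 40, air_velocity = 0.40)
    }
  }
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, nrow(geometry)), geometry$zone)
    }
    miss <- setdiff(geometry$zone, names(x))
    if (length(miss) > 0L) stop("truth missing zone(s): ",
                                paste(miss, collapse = ", "), call. = FALSE)
    x[geometry$zone]
  }
  if (mode == "dry") {
    if (environment$operative_temperature >= setpoint) {
      stop("dry mode needs operative temperature below the set-point",
           call. = FALSE)
    }
    truth <- expand(true_zone_insulation)
    stopifnot(all(truth > 0))
  } else {
    if (abs(environment$air_temperature - setpoint) > 0.5) {
      stop("wet mode needs an isothermal environment (air ~ set-point)",
           call. = FALSE)
    }
    truth <- expand(true_zone_evap_resistance)
    stopifnot(all(truth > 0))
  }
  stopifnot(duration > 0, sample_interval > 0, warmup_time_constant >= 0,
            noise_sd_temp >= 0, noise_sd_flux_fraction >= 0)
  structure(
    list(mode = mode, geometry = geometry, truth = truth,
         environment = environment, setpoint = setpoint, skin_rh = skin_rh,
         noise_sd_temp = noise_sd_temp,
         noise_sd_flux_fraction = noise_sd_flux_fraction,
         duration = duration, sample_interval = sample_interval,
         warmup_time_constant = warmup_time_constant,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Steady zone heat losses implied by the spec's ground truth (W).
# Wet mode iterates the flux/skin-temperature fixed point with damping.
steady_zone_losses <- function(spec) {
  geo <- spec$geometry
  if (spec$mode == "dry") {
    grad <- spec$setpoint - spec$environment$operative_temperature
    return(stats::setNames(grad * geo$area / spec$truth, geo$zone))
  }
  p_a <- vapour_pressure(spec$environment$air_temperature,
                         spec$environment$relative_humidity)
  flux <- numeric(nrow(geo))
  for (i in seq_len(nrow(geo))) {
    r <- spec$truth[i]
    q <- (vapour_pressure(spec$setpoint, spec$skin_rh) - p_a) / r
    trace <- q
    converged <- FALSE
    for (iter in seq_len(50L)) {
      tsk <- corrected_skin_temperature(spec$setpoint, q)
      q_new <- (vapour_pressure(tsk, spec$skin_rh) - p_a) / r
      q_next <- 0.5 * q + 0.5 * q_new  # damped iteration
      trace <- c(trace, q_next)
      if (abs(q_next - q) < 1e-6) { q <- q_next; converged <- TRUE; break }
      q <- q_next
    }
    if (!converged) {
      stop("wet fixed point did not converge for zone ", geo$zone[i],
           "; flux trace: ", paste(signif(trace, 6), collapse = " -> "),
           call. = FALSE)
    }
    flux[i] <- q
  }
  stats::setNames(flux * geo$area, geo$zone)
}

# Whole-body ground truth implied by the spec, as the reduction measures it
# at noise-free steady state: global-method I_T (dry) or corrected R_et (wet).
true_whole_body <- function(spec) {
  geo <- spec$geometry
  losses <- steady_zone_losses(spec)
  total_area <- attr(geo, "total_area")
  if (spec$mode == "dry") {
    (spec$setpoint - spec$environment$operative_temperature) *
      total_area / sum(losses)
  } else {
    tsk <- corrected_skin_temperature(spec$setpoint, losses / geo$area)
    mean_tsk <- sum(tsk * geo$area) / total_area
    p_sk <- vapour_pressure(mean_tsk, spec$skin_rh)
    p_a <- vapour_pressure(spec$environment$air_temperature,
                           spec$environment$relative_humidity)
    (p_sk - p_a) * total_area / sum(losses)
  }
}

#' Generate a synthetic manikin trial
#'
#' Simulates the time series of a trial from its [synthetic_spec()]: zone
#' heat losses approach the truth-implied steady value exponentially (the
#' warm-up), surface temperatures sit at the set-point, and both carry
#' i.i.d. Gaussian sensor noise. Identical spec and seed give a
#' bit-identical trial.
#'
#' @param spec a [synthetic_spec()].
#' @return A [manikin_trial()].
#' @examples
#' trial <- generate_trial(synthetic_spec(mode = "dry", seed = 42))
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  geo <- spec$geometry
  steady <- steady_zone_losses(spec)
  times <- seq(0, spec$duration, by = spec$sample_interval)
  n_t <- length(times)
  n_z <- nrow(geo)
  # warm-up: flux starts 50% above steady (cold chamber start-up transient)
  ramp <- if (spec$warmup_time_constant > 0) {
    1 + 0.5 * exp(-times / spec$warmup_time_constant)
  } else rep(1, n_t)
  loss_mat <- outer(ramp, steady)          # n_t x n_z
  set.seed(spec$seed)
  if (spec$noise_sd_flux_fraction > 0) {
    loss_mat <- loss_mat + matrix(
      stats::rnorm(n_t * n_z, sd = spec$noise_sd_flux_fraction * rep(steady, each = n_t)),
      n_t, n_z)
  }
  temp_mat <- matrix(spec$setpoint, n_t, n_z)
  if (spec$noise_sd_temp > 0) {
    temp_mat <- temp_mat + matrix(stats::rnorm(n_t * n_z, sd = spec$noise_sd_temp),
                                  n_t, n_z)
  }
  data <- tibble::tibble(
    time_s = rep(times, times = n_z),
    zone = rep(geo$zone, each = n_t),
    surface_temp_C = as.vector(temp_mat),
    heat_loss_W = as.vector(loss_mat)
  )
  manikin_trial(
    trial_id = sprintf("synthetic-%s-seed%d", spec$mode, spec$seed),
    mode = spec$mode, geometry = geo, environment = spec$environment,
    data = data,
    skin_rh = if (spec$mode == "wet") spec$skin_rh else NULL
  )
}

#' Parameter-recovery experiment
#'
#' Generates `n_seeds` independent trials from a spec (seeds `spec$seed`,
#' `spec$seed + 1`, ...), runs the matching reduction on each (steady-state
#' detection, window averaging, global-method whole-body insulation or
#' corrected whole-body evaporative resistance), and summarises the bias
#' and spread of the estimates against the truth implied by the spec.
#'
#' @param spec a [synthetic_spec()].
#' @param n_seeds number of independent replicates, >= 2.
#' @param min_duration,slope_tolerance,cv_tolerance steady-state criteria
#'   passed to [detect_steady_state()].
#' @return A `recovery_result`: list with `true_value`, `estimates`,
#'   `relative_errors`, `estimated_value` (their mean), `relative_error`
#'   (of the mean), `error_mean`, `error_sd`, `n_seeds`.
#' @examples
#' recovery_experiment(synthetic_spec(mode = "dry", duration = 1800), n_seeds = 3)
#' @export
recovery_experiment <- function(spec, n_seeds, min_duration = 600,
                                slope_tolerance = 0.005, cv_tolerance = 0.02) {
  stopifnot(inherits(spec, "synthetic_spec"), n_seeds >= 2)
  truth <- true_whole_body(spec)
  estimates <- vapply(seq_len(n_seeds) - 1L, function(k) {
    sp <- spec
    sp$seed <- spec$seed + k
    trial <- generate_trial(sp)
    window <- detect_steady_state(trial, min_duration, slope_tolerance,
                                  cv_tolerance)
    steady <- average_window(trial, window)
    if (spec$mode == "dry") {
      whole_body_total_insulation(steady, method = "global")
    } else {
      whole_body_evap_resistance(steady)$ret
    }
  }, numeric(1))
  rel <- (estimates - truth) / truth
  structure(
    list(true_value = truth, estimates = estimates, relative_errors = rel,
         estimated_value = mean(estimates),
         relative_error = (mean(estimates) - truth) / truth,
         error_mean = mean(rel), error_sd = stats::sd(rel),
         n_seeds = n_seeds),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> truth=%.4g  mean est=%.4g  bias=%.3f%%  sd=%.3f%%  (n=%d)\n",
              x$true_value, x$estimated_value, 100 * x$error_mean,
              100 * x$error_sd, x$n_seeds))
  invisible(x)
}
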