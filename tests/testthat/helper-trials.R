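# Small builders used across the suite.

# Two-zone geometry with simple areas for hand-checkable arithmetic.
tiny_geometry <- function(areas = c(a = 0.5, b = 0.5)) {
  manikin_geometry(names(areas), unname(areas))
}

dry_env <- function(air = 20) {
  manikin_environment(air, relative_humidity = 50, air_velocity = 0.18)
}

wet_env <- function() {
  manikin_environment(34, relative_humidity = 40, air_velocity = 0.40)
}

# Trial from per-zone functions of time: temp_fun / loss_fun take the time
# vector and a zone index and return the series for that zone.
make_trial <- function(times, geometry, temp_fun, loss_fun,
                       mode = "dry", environment = dry_env(),
                       skin_rh = NULL, trial_id = "test") {
  zones <- geometry$zone
  data <- do.call(rbind, lapply(seq_along(zones), function(i) {
    data.frame(time_s = times, zone = zones[i],
               surface_temp_C = temp_fun(times, i),
               heat_loss_W = loss_fun(times, i))
  }))
  manikin_trial(trial_id, mode, geometry, environment, data,
                skin_rh = skin_rh)
}

constant_trial <- function(times = seq(0, 1200, by = 10),
                           geometry = tiny_geometry(),
                           temp = 34, loss = 100, ...) {
  make_trial(times, geometry,
             temp_fun = function(t, i) rep(temp, length(t)),
             loss_fun = function(t, i) rep(loss, length(t)), ...)
}

# Steady object straight from zone means, bypassing time series.
steady_from_means <- function(temps, losses, geometry,
                              environment = dry_env(), mode = "dry",
                              skin_rh = NULL) {
  structure(
    list(zone_means = tibble::tibble(zone = geometry$zone,
                                     surface_temp_C = temps,
                                     heat_loss_W = losses),
         environment = environment, geometry = geometry, mode = mode,
         skin_rh = skin_rh, n_samples = 1L,
         window = list(start_time = 0, end_time = 1)),
    class = "manikin_steady"
  )
}
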