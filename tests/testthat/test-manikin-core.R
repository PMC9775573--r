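test_that("geometry validates zones and areas and sums the total", {
  geo <- default_geometry()
  expect_equal(nrow(geo), 17L)
  expect_setequal(geo$zone, MANIKIN_ZONES)
  expect_equal(attr(geo, "total_area"), sum(geo$area), tolerance = 1e-12)
  expect_equal(attr(geo, "total_area"), 1.77, tolerance = 1e-9)
  expect_error(manikin_geometry(c("a", "a"), c(1, 1)), "unique")
  expect_error(manikin_geometry(c("a", "b"), c(1, -1)), "positive")
  rescaled <- default_geometry(total_area = 2.0)
  expect_equal(attr(rescaled, "total_area"), 2.0, tolerance = 1e-12)
})

test_that("operative temperature equals air temperature when radiant does", {
  env <- manikin_environment(20, relative_humidity = 40, air_velocity = 0.2)
  expect_equal(env$operative_temperature, 20)
  env2 <- manikin_environment(20, radiant_temperature = 30,
                              relative_humidity = 40, air_velocity = 0.2)
  expect_equal(env2$operative_temperature, 25)
  expect_error(manikin_environment(20, relative_humidity = 120,
                                   air_velocity = 0.2), "0, 100")
})

test_that("trial construction enforces zone coverage and time ordering", {
  geo <- tiny_geometry()
  tr <- constant_trial(geometry = geo)
  expect_s3_class(tr, "manikin_trial")
  bad <- tr$data[-1, ]  # drop one sample: coverage broken
  expect_error(manikin_trial("x", "dry", geo, dry_env(), bad),
               "exactly one sample per")
  expect_error(manikin_trial("x", "dry", geo, dry_env(), tr$data,
                             skin_rh = 96), "skin_rh")
})

test_that("a constant series yields the final window of the requested length", {
  tr <- constant_trial(times = seq(0, 1800, by = 10))
  w <- detect_steady_state(tr, min_duration = 600)
  expect_equal(w$end_time, 1800)
  expect_equal(w$start_time, 1200)
})

test_that("exponential approach to plateau steadies only after the transient", {
  times <- seq(0, 4200, by = 10)
  tau <- 300
  tr <- make_trial(times, tiny_geometry(),
                   temp_fun = function(t, i) rep(34, length(t)),
                   loss_fun = function(t, i) 100 * (1 + 0.5 * exp(-t / tau)))
  w <- detect_steady_state(tr, min_duration = 600, slope_tolerance = 0.005)
  expect_gt(w$start_time, 3 * tau)
  expect_equal(w$end_time, 4200)
  # at the detected window the analytic curve's relative trend is inside tol
  expect_lt(0.5 * exp(-w$start_time / tau) / tau * 60, 0.005)
})

test_that("white-noise series are detected and averaged without bias", {
  n_hit <- 0
  for (seed in 1:100) {
    set.seed(seed)
    times <- seq(0, 900, by = 10)
    tr <- make_trial(times, tiny_geometry(),
                     temp_fun = function(t, i) 34 + rnorm(length(t), sd = 0.02),
                     loss_fun = function(t, i) rnorm(length(t), 100, 1))
    w <- detect_steady_state(tr, min_duration = 600, slope_tolerance = 0.01,
                             cv_tolerance = 0.05)
    st <- average_window(tr, w)
    m <- mean(st$zone_means$heat_loss_W)
    n <- st$n_samples * 2  # two zones
    if (abs(m - 100) <= 3 * 1 / sqrt(n)) n_hit <- n_hit + 1
  }
  expect_gte(n_hit, 95)
})

test_that("monotone diverging series has no steady state", {
  times <- seq(0, 1800, by = 10)
  tr <- make_trial(times, tiny_geometry(),
                   temp_fun = function(t, i) rep(34, length(t)),
                   loss_fun = function(t, i) 50 + 0.05 * t)
  expect_error(detect_steady_state(tr, min_duration = 600), "no steady state")
})

test_that("window averages match closed forms", {
  geo <- tiny_geometry()
  times <- seq(0, 1000, by = 10)
  # constant: idempotent
  tr <- constant_trial(times = times, geometry = geo, loss = 42)
  st <- average_window(tr, list(start_time = 0, end_time = 1000))
  expect_equal(st$zone_means$heat_loss_W, c(42, 42))
  # linear ramp a + b t: discrete mean is a + b * mean(t)
  a <- 80; b <- 0.01
  tr2 <- make_trial(times, geo,
                    temp_fun = function(t, i) rep(34, length(t)),
                    loss_fun = function(t, i) a + b * t)
  st2 <- average_window(tr2, list(start_time = 0, end_time = 1000))
  expect_equal(st2$zone_means$heat_loss_W[1], a + b * mean(times),
               tolerance = 1e-12)
  # sub-window selection
  st3 <- average_window(tr2, list(start_time = 500, end_time = 1000))
  expect_equal(st3$zone_means$heat_loss_W[1], a + b * 750, tolerance = 1e-12)
  expect_error(average_window(tr2, list(start_time = 900, end_time = 900)),
               "positive duration")
})

test_that("averaging is linear in the sample values", {
  geo <- tiny_geometry()
  times <- seq(0, 600, by = 10)
  set.seed(11)
  y1 <- rnorm(length(times), 100, 5)
  y2 <- rnorm(length(times), 50, 2)
  mk <- function(y) make_trial(times, geo,
                               temp_fun = function(t, i) rep(34, length(t)),
                               loss_fun = function(t, i) y)
  win <- list(start_time = 0, end_time = 600)
  m <- function(y) average_window(mk(y), win)$zone_means$heat_loss_W[1]
  expect_equal(m(2 * y1 + 3 * y2), 2 * m(y1) + 3 * m(y2), tolerance = 1e-10)
})

test_that("repeatability rule uses the mean-normalised difference", {
  r <- repeatability_check(0.100, 0.103)
  expect_equal(r$relative_difference, 0.003 / 0.1015, tolerance = 1e-12)
  expect_true(r$pass)  # 2.96%
  r2 <- repeatability_check(0.100, 0.105)
  expect_equal(round(100 * r2$relative_difference, 2), 4.88)
  expect_false(r2$pass)
  # identity and symmetry
  expect_equal(repeatability_check(0.3, 0.3)$relative_difference, 0)
  expect_true(repeatability_check(0.3, 0.3)$pass)
  expect_equal(repeatability_check(0.2, 0.25)$relative_difference,
               repeatability_check(0.25, 0.2)$relative_difference)
  # equality at the threshold passes
  expect_true(repeatability_check(1, 1, threshold_fraction = 0)$pass)
  expect_error(repeatability_check(-1, 1), "positive")
})

test_that("mean surface temperature is the area-weighted mean", {
  geo <- tiny_geometry(c(a = 0.5, b = 0.5))
  expect_equal(mean_surface_temperature(c(a = 34, b = 34), geo), 34)
  expect_equal(mean_surface_temperature(c(a = 30, b = 38), geo), 34)
  # random case against an independent weighted-sum oracle; bounded by range
  set.seed(4)
  for (k in 1:20) {
    n <- sample(3:8, 1)
    areas <- runif(n, 0.05, 0.3)
    temps <- runif(n, 28, 38)
    zs <- paste0("z", seq_len(n))
    geo_k <- manikin_geometry(zs, areas)
    oracle <- sum(temps * areas) / sum(areas)
    got <- mean_surface_temperature(setNames(temps, zs), geo_k)
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_gte(got, min(temps))
    expect_lte(got, max(temps))
  }
  expect_error(mean_surface_temperature(c(a = 34), geo), "missing temperature")
})
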