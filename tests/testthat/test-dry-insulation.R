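test_that("zone insulation and contribution follow the defining quotients", {
  expect_equal(zone_total_insulation(34, 10, 0.1, 12), 0.2)
  expect_equal(zone_total_insulation(34, 20, 0.1, 14), 0.1)
  expect_error(zone_total_insulation(20, 34, 0.1, 12, zone = "head"), "head")
  expect_equal(zone_contribution(0.2, 0.1, 2.0), 0.01)
  # heterogeneous contributions vs brute-force weighted sum
  it <- c(0.2, 0.35, 0.15); a <- c(0.3, 0.5, 0.2)
  expect_equal(sum(zone_contribution(it, a, sum(a))),
               sum(a / sum(a) * it), tolerance = 1e-15)
})

test_that("group insulation reduces to the zone formula and to the whole body", {
  geo <- tiny_geometry(c(a = 0.2, b = 0.3))
  st <- steady_from_means(c(34, 34), c(10, 20), geo, dry_env(20))
  # two-zone hand arithmetic: (14 x 0.5) / 30
  expect_equal(group_total_insulation(st, c("a", "b")), 14 * 0.5 / 30,
               tolerance = 1e-12)
  # single-zone group equals the zone quotient
  expect_equal(group_total_insulation(st, "a"),
               zone_total_insulation(34, 20, 0.2, 10), tolerance = 1e-15)
  # all-zone group reproduces the global whole-body form
  set.seed(9)
  geo3 <- manikin_geometry(c("x", "y", "z"), runif(3, 0.1, 0.4))
  st3 <- steady_from_means(runif(3, 30, 36), runif(3, 5, 25), geo3, dry_env(10))
  expect_equal(group_total_insulation(st3, geo3$zone),
               whole_body_total_insulation(st3, "global"), tolerance = 1e-12)
  expect_error(group_total_insulation(st, character(0)), "non-empty")
  expect_error(group_total_insulation(st, "nope"), "not in geometry")
})

test_that("serial, parallel and global methods relate as the theory says", {
  # homogeneous inputs: all three coincide
  geo <- tiny_geometry(c(a = 0.4, b = 0.6))
  st <- steady_from_means(c(34, 34), c(34 - 20) * geo$area / 0.25,
                          geo, dry_env(20))
  for (m in c("global", "serial", "parallel")) {
    expect_equal(whole_body_total_insulation(st, m), 0.25, tolerance = 1e-12)
  }
  # heterogeneous with uniform surface temperature: global == parallel,
  # serial >= global (area-weighted AM-HM)
  set.seed(21)
  for (k in 1:25) {
    n <- sample(3:17, 1)
    geo_k <- manikin_geometry(paste0("z", 1:n), runif(n, 0.05, 0.3))
    it_true <- runif(n, 0.1, 0.6)
    losses <- (34 - 10) * geo_k$area / it_true
    st_k <- steady_from_means(rep(34, n), losses, geo_k, dry_env(10))
    g <- whole_body_total_insulation(st_k, "global")
    p <- whole_body_total_insulation(st_k, "parallel")
    s <- whole_body_total_insulation(st_k, "serial")
    expect_equal(g, p, tolerance = 1e-12)
    expect_gte(s, g - 1e-12)
  }
})

test_that("serial equals parallel only for equal zone insulations", {
  geo <- tiny_geometry(c(a = 0.5, b = 0.5))
  st <- steady_from_means(c(34, 34), (34 - 20) * geo$area / c(0.2, 0.4),
                          geo, dry_env(20))
  expect_gt(whole_body_total_insulation(st, "serial"),
            whole_body_total_insulation(st, "parallel") + 1e-6)
})

test_that("basic insulation removes the scaled air layer", {
  expect_equal(round(basic_insulation(0.187, 0.099, 1.19), 3), 0.104)
  expect_equal(round(basic_insulation(0.477, 0.099, 1.68), 3), 0.418)
  expect_equal(basic_insulation(0.099, 0.099, 1.0), 0)  # nude identity
  expect_error(basic_insulation(0.2, 0.1, 0.9), "fcl")
  expect_warning(basic_insulation(0.08, 0.099, 1.0), "negative")
  # monotone in total, antitone in air layer
  expect_gt(basic_insulation(0.3, 0.099, 1.2), basic_insulation(0.2, 0.099, 1.2))
  expect_lt(basic_insulation(0.3, 0.12, 1.2), basic_insulation(0.3, 0.09, 1.2))
})

test_that("clo conversion is the 0.155 scaling and round-trips", {
  expect_equal(to_clo(0.155), 1)
  expect_equal(round(to_clo(basic_insulation(0.187, 0.099, 1.19)), 2), 0.67)
  # the heaviest ensemble's printed clo was derived from unrounded SI
  # inputs; recomputation from the printed row lands one last digit up
  expect_equal(round(to_clo(basic_insulation(0.477, 0.099, 1.68)), 2), 2.70)
  expect_lt(abs(to_clo(basic_insulation(0.477, 0.099, 1.68)) - 2.69), 0.01)
  x <- runif(10, 0, 1)
  expect_equal(from_clo(to_clo(x)), x, tolerance = 1e-15)
})

test_that("the dry pipeline inverts a noise-free generated zone exactly", {
  sp <- synthetic_spec(mode = "dry", true_zone_insulation = 0.35,
                       noise_sd_temp = 0, noise_sd_flux_fraction = 0,
                       warmup_time_constant = 0, duration = 1200, seed = 1)
  res <- compute_insulation(generate_trial(sp))
  expect_equal(res$total_insulation, 0.35, tolerance = 1e-12)
  expect_equal(unname(res$zone_values), rep(0.35, 17), tolerance = 1e-12)
  expect_equal(sum(res$zone_contributions), 0.35, tolerance = 1e-12)
  expect_equal(res$method, "global")
})

test_that("basic-insulation identity holds on the full result object", {
  sp <- synthetic_spec(mode = "dry", true_zone_insulation = 0.187,
                       noise_sd_temp = 0, noise_sd_flux_fraction = 0,
                       warmup_time_constant = 0, duration = 1200, seed = 1)
  res <- compute_insulation(generate_trial(sp), fcl = 1.19)
  expect_equal(res$basic_insulation,
               res$total_insulation - res$air_layer_insulation /
                 res$clothing_area_factor,
               tolerance = 1e-12)
  expect_gte(res$basic_insulation, 0)
})

test_that("recomputing the packaged basic-insulation columns reproduces print", {
  wdb <- load_wardrobe()
  ia <- wdb$reference$ensembles$it[wdb$reference$ensembles$code == "AL"]
  items_dev <- basic_insulation(wdb$items$it, ia, wdb$items$fcl) - wdb$items$iclu
  expect_lt(max(abs(items_dev)), 0.0015)
  ens_dev <- basic_insulation(wdb$ensembles$it, ia, wdb$ensembles$fcl) -
    wdb$ensembles$icl_si
  expect_lt(max(abs(ens_dev)), 0.0015)
})
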