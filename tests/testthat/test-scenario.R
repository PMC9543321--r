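test_that("delay multiplier reproduces the reported media factors", {
  expect_equal(round(delay_multiplier(0.06, 6, 1), 2), 0.70)
  expect_equal(delay_multiplier(0.06, 6, 0), 1)
  # formula inversion: the 0.81 upper-station multiplier implies f_adj ~ 0.63
  f <- (1 - 0.81) / (1 - exp(-0.36))
  expect_equal(f, 0.63, tolerance = 0.01)
  expect_equal(delay_multiplier(0.06, 6, f), 0.81, tolerance = 1e-12)
})

test_that("delay multiplier is monotone decreasing in f_adj, lambda and delay", {
  expect_true(all(diff(delay_multiplier(0.06, 6, seq(0, 1, 0.1))) < 0))
  expect_true(all(diff(delay_multiplier(seq(0.01, 0.2, 0.01), 6, 0.5)) < 0))
  expect_true(all(diff(delay_multiplier(0.06, 1:15, 0.5)) < 0))
  expect_error(delay_multiplier(0.06, 6, 1.2), "0, 1")
})

test_that("the default adjustment spec rounds to the reported fish multipliers", {
  a <- adjustment_spec()
  expect_equal(round(a$water_multiplier, 2), 0.70)
  expect_equal(unname(round(a$fish_multipliers, 2)), c(0.81, 0.83, 0.89))
  expect_true(all(a$fish_multipliers >= a$water_multiplier &
                    a$fish_multipliers <= 1))
})

test_that("alternative definitions respect their structural invariants", {
  expect_false(remedy_alternative(1)$stf_active)      # STF removed
  a2 <- remedy_alternative(2)
  expect_true(a2$stf_active && !a2$sediment_removal && !a2$nsb_captured)
  a3 <- remedy_alternative(3)
  expect_true(a3$sediment_removal && a3$nsb_captured)
  expect_gt(a3$outfall_mile, a2$outfall_mile)         # relocated downstream
  caps <- vapply(4:7, function(i) remedy_alternative(i)$capacity_gpm, 0)
  store <- vapply(4:7, function(i) remedy_alternative(i)$storage_gal, 0)
  expect_true(all(diff(store) > 0) && max(store) == 13e6)
  expect_true(all(caps >= 450) && max(caps) == 1000)
  expect_error(remedy_alternative(8), "unknown")
})

test_that("alternative 2 leaves the configuration unchanged; 3 dredges and captures", {
  cfg <- default_site_config()
  c2 <- apply_alternative(cfg, 2)
  for (f in c("stf", "bed_conc", "nsb_captured", "spring", "fate"))
    expect_identical(c2[[f]], cfg[[f]])
  c3 <- apply_alternative(cfg, 3)
  expect_equal(unname(c3$bed_conc["CB"]), cfg$dredge_residual)
  expect_true(c3$nsb_captured)
})

test_that("the STF fill-spill reservoir conserves water and captures storms with storage", {
  set.seed(9)
  flow <- 0.05 * (1 + c(rep(0, 10), 400 * exp(-(0:19) / 2), rep(0, 10)))
  conc <- rep(200, length(flow))
  stf0 <- list(active = TRUE, capacity_gpm = 450, storage_gal = 0,
               capture_frac = 0.85, removal = 0.99)
  stf_big <- modifyList(stf0, list(capacity_gpm = 1000, storage_gal = 13e6))
  p0 <- stf_partition(flow, conc, stf0)
  pb <- stf_partition(flow, conc, stf_big)
  # water balance: inflow = untreated + treated + basin storage change
  for (p in list(p0, pb)) {
    lhs <- sum(flow) * 86400
    rhs <- sum(p$untreated_flow + p$treated_flow) * 86400 +
      utils::tail(p$basin_volume, 1)
    expect_equal(lhs, rhs, tolerance = 1e-9 * lhs)
  }
  # storage + capacity treat more of the storm load
  expect_lt(sum(pb$untreated_load), sum(p0$untreated_load))
  # inactive STF passes everything through untreated
  off <- stf_partition(flow, conc, list(active = FALSE))
  expect_equal(off$untreated_load, flow * 86400 * conc)
})

test_that("bounding calibration sets shift parameters in opposite directions", {
  b <- calibration_set("base"); u <- calibration_set("upper")
  l <- calibration_set("lower")
  for (f in c("decay_factor", "nsb_factor", "storm_factor",
              "sed_exchange_factor", "volat_factor", "benthic_diet_factor"))
    expect_true((u[[f]] - b[[f]]) * (l[[f]] - b[[f]]) < 0 ||
                  (u[[f]] == 1 && l[[f]] == 1), label = f)
  cfgu <- apply_calibration(default_site_config(), u)
  expect_lt(cfgu$spring$lambda, 0.06)     # slower recovery on the upper bound
  d <- cfgu$species$creek_chub$diet_by_month
  expect_true(all(abs(rowSums(d) - 1) < 1e-12))
  expect_true(all(d >= 0))
})

test_that("identical seeds give identical short projections", {
  cfg <- default_site_config()
  p1 <- run_projection(cfg, 3, "base", years = 1, seed = 11)
  p2 <- run_projection(cfg, 3, "base", years = 1, seed = 11)
  expect_identical(p1$water, p2$water)
  expect_identical(p1$year10, p2$year10)
  p3 <- run_projection(cfg, 3, "base", years = 1, seed = 12)
  expect_false(identical(p1$water, p3$water))
})

test_that("the delay adjustment scales a projection's media as specified", {
  cfg <- default_site_config()
  p <- run_projection(cfg, 3, "base", years = 1, seed = 5)
  a <- adjustment_spec()
  pa <- adjust_projection(p, a)
  expect_equal(pa$water$cw, p$water$cw * a$water_multiplier)
  k <- "CBVP.creek_chub"
  expect_equal(pa$fish[[k]]$series$conc,
               p$fish[[k]]$series$conc *
                 a$fish_multipliers[["CBVP.creek_chub"]])
})
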