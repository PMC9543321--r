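test_that("equilibrium dissolved fraction follows Kp * TSS", {
  expect_equal(dissolved_fraction(0, 1e5), 1)
  expect_equal(dissolved_fraction(10, 1e5), 0.5)     # Kp*TSS = 1
  expect_equal(dissolved_fraction(10, 1e12), 0, tolerance = 1e-6)
  # monotone decreasing in Kp at fixed TSS
  kps <- 10^seq(3, 7, by = 0.5)
  expect_true(all(diff(dissolved_fraction(10, kps)) < 0))
})

test_that("dilution-only steady state equals load over flow", {
  net <- default_network()
  hyd <- steady_hydro(net, spring = 0.05, rc = 0.35, nd = 40)
  n <- nrow(net$cells)
  W <- 5e5                                           # ug/d into the head cell
  loads <- matrix(0, 40, n); loads[, 1] <- W
  pars <- fate_params(v_s = 0, k_v = 0, k_f = 0, M_e = 0, D_b = 0, v_b = 0)
  ft <- simulate_fate(net, hyd, loads, matrix(0, 40, n), pars,
                      bed_state(net, conc_active = 0), tss0 = 0)
  # checked away from the confluence, where dispersion sees no gradient
  expect_equal(ft$cw[40, 10], W / (0.05 * 86400), tolerance = 1e-6)
  expect_equal(ft$cw[40, 38], W / (0.40 * 86400), tolerance = 1e-6)
})

test_that("volatilization-only closed cell decays as the analytic exponential", {
  cc <- closed_cell(depth = 0.5, nd = 2)
  z <- matrix(0, 2, 1)
  pars <- fate_params(v_s = 0, k_v = 1, k_f = 0, M_e = 0)
  ft <- simulate_fate(cc$network, cc$hydro, z, z, pars,
                      bed_state(cc$network, conc_active = 0),
                      cw0 = 100, tss0 = 0)
  # k_v/h = 2/d, so C(1 d)/C(0) = exp(-2)
  expect_equal(ft$cw[1, 1] / 100, exp(-2), tolerance = 0.01)
  expect_equal(ft$cw[2, 1] / 100, exp(-4), tolerance = 0.01)
})

test_that("the PCB mass budget closes on a storm-driven year", {
  ci <- calib_inputs(years = 1, seed = 3)
  bed <- bed_state(ci$net, conc_active = c(CB = 8, RC = 2))
  ft <- simulate_fate(ci$net, ci$hydro, Reduce(`+`, ci$loads), ci$tss,
                      fate_params(), bed)
  expect_lt(ft$budget$rel_error, 0.005)
  # configuration check: settling in the upper stream is a sub-percent
  # share of its loads and volatilization a few percent
  cb <- which(ci$net$cells$reach == "CB")
  expect_lt(sum(ft$budget$settled_by_cell[cb]) / ft$budget$loads_in, 0.02)
  vol_share <- sum(ft$budget$volatilized_by_cell[cb]) / ft$budget$loads_in
  expect_gt(vol_share, 0.003); expect_lt(vol_share, 0.10)
})

test_that("increasing the settling velocity increases the settling share", {
  ci <- calib_inputs(years = 1, seed = 3)
  bed <- bed_state(ci$net, conc_active = 0)
  loads <- Reduce(`+`, ci$loads)
  shares <- vapply(c(0.3, 1.2), function(vs) {
    ft <- simulate_fate(ci$net, ci$hydro, loads, ci$tss,
                        fate_params(v_s = vs), bed)
    ft$budget$settled / ft$budget$loads_in
  }, 0)
  expect_gt(shares[2], shares[1])
})

test_that("storm loads largely flow through the upper stream (short residence)", {
  ci <- calib_inputs(years = 1, seed = 3)
  bed <- bed_state(ci$net, conc_active = 0)
  ft <- simulate_fate(ci$net, ci$hydro, ci$loads$spring, ci$tss,
                      fate_params(), bed)
  cb <- which(ci$net$cells$reach == "CB")
  dep_cb <- sum(ft$budget$settled_by_cell[cb])
  expect_lt(dep_cb, 0.05 * ft$budget$loads_in)
  expect_gt(ft$budget$exported, 0.5 * ft$budget$loads_in)
})

test_that("per-source runs superpose and fractions sum to one", {
  ci <- calib_inputs(years = 1, seed = 3)
  bed <- bed_state(ci$net, conc_active = c(CB = 8, RC = 2))
  ap <- apportion_sources(ci$net, ci$hydro, ci$loads, ci$tss,
                          fate_params(), bed,
                          station_miles = c(CBVP = 0.74, RCVP = 1.05))
  expect_lt(ap$superposition_error, 1e-6)
  expect_equal(unname(rowSums(ap$water_fractions)), c(1, 1),
               tolerance = 1e-6)
  expect_equal(unname(rowSums(ap$bed_fractions)), c(1, 1),
               tolerance = 1e-6)
  # doubling one source doubles its absolute contribution
  ci2 <- ci; ci2$loads$nsb <- 2 * ci$loads$nsb
  ap2 <- apportion_sources(ci2$net, ci2$hydro, ci2$loads, ci2$tss,
                           fate_params(), bed,
                           station_miles = c(CBVP = 0.74))
  expect_equal(colMeans(ap2$runs$nsb$cw), 2 * colMeans(ap$runs$nsb$cw),
               tolerance = 1e-9)
})

test_that("a lone source accounts for everything it reaches; apportionment refuses nonlinear mode", {
  net <- default_network()
  hyd <- steady_hydro(net, nd = 20)
  n <- nrow(net$cells)
  one <- matrix(0, 20, n); one[, 1] <- 1e5
  bed0 <- bed_state(net, conc_active = 0)
  ap <- apportion_sources(net, hyd, list(only = one), matrix(0, 20, n),
                          fate_params(), bed0,
                          station_miles = c(MID = 1.5))
  expect_equal(unname(ap$water_fractions["MID", "only"]), 1,
               tolerance = 1e-9)
  # two identical co-located sources split 50/50
  ap2 <- apportion_sources(net, hyd, list(a = one, b = one),
                           matrix(0, 20, n), fate_params(), bed0,
                           station_miles = c(MID = 1.5))
  expect_equal(unname(ap2$water_fractions["MID", ]), c(0.5, 0.5),
               tolerance = 1e-9)
  expect_error(
    apportion_sources(net, hyd, list(a = one), matrix(0, 20, n),
                      fate_params(nonlinear = TRUE), bed0,
                      station_miles = c(MID = 1.5)),
    "superposition")
})

test_that("an infeasibly fast exchange rate aborts with a diagnostic", {
  net <- default_network()
  hyd <- steady_hydro(net, nd = 10)
  n <- nrow(net$cells)
  bed <- bed_state(net, conc_active = 5, thickness_active = 1e-4)
  expect_error(
    simulate_fate(net, hyd, matrix(0, 10, n), matrix(0, 10, n),
                  fate_params(k_f = 500), bed),
    "negative state")
})
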