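test_that("Manning depth inversion matches a bisection oracle and round-trips", {
  # independent oracle: bisection on the forward Manning relation
  oracle <- function(q, w, s, n) {
    stats::uniroot(function(h) manning_flow(h, width = w, slope = s,
                                            roughness = n) - q,
                   c(1e-6, 50), tol = 1e-12)$root
  }
  h <- solve_depth(9.335, width = 10, slope = 0.001, roughness = 0.030)
  expect_equal(h, oracle(9.335, 10, 0.001, 0.030), tolerance = 1e-8)
  expect_equal(h, 1.00, tolerance = 1e-3)

  # property: round-trip over random geometries and depths
  set.seed(42)
  for (i in 1:20) {
    w <- runif(1, 0.5, 30); s <- 10^runif(1, -4, -2)
    n <- runif(1, 0.02, 0.08); h0 <- 10^runif(1, -2, 0.7)
    q <- manning_flow(h0, width = w, slope = s, roughness = n)
    expect_equal(solve_depth(q, width = w, slope = s, roughness = n), h0,
                 tolerance = 1e-6)
  }
  expect_identical(solve_depth(0, width = 5, slope = 0.001,
                               roughness = 0.03), 0)
  expect_error(solve_depth(-1, width = 5, slope = 0.001, roughness = 0.03),
               "non-negative")
})

test_that("default geometry reproduces the observed base-flow depths", {
  net <- default_network()
  # ~6 ft wide, ~0.6 ft deep at upper-stream base flow
  h_cb <- solve_depth(0.05, reach = net$reaches[[1]])
  expect_equal(h_cb / 0.3048, 0.6, tolerance = 0.05)
  # ~15 ft wide, ~0.9 ft deep below the confluence
  h_rc <- solve_depth(0.40, reach = net$reaches[[2]])
  expect_equal(h_rc / 0.3048, 0.9, tolerance = 0.05)
})

test_that("quasi-steady routing conserves flow and sums at the confluence", {
  net <- default_network()
  hyd <- steady_hydro(net, spring = 1, rc = 0, nd = 5)
  expect_true(all(hyd$Q == 1))                      # single-inflow transit
  hyd2 <- steady_hydro(net, spring = 0.05, rc = 0.35, nd = 5)
  cb <- net$cells$reach == "CB"
  expect_equal(max(abs(hyd2$Q[, cb] - 0.05)), 0)
  expect_equal(max(abs(hyd2$Q[, !cb] - 0.40)), 0,   # tributary flows add
               tolerance = 1e-12)
  expect_true(all(hyd2$velocity * hyd2$area - hyd2$Q < 1e-12))
})

test_that("a 1000-fold storm hydrograph propagates to a 1000-fold peak flow", {
  net <- default_network()
  base <- 0.05
  storm <- base * c(1, 1, 1000, 1, 1)
  fm <- cbind(spring = storm, rc_upstream = rep(0.35, 5))
  hyd <- route_flow(net, fm, c(spring = 0, rc_upstream = 0.8))
  expect_equal(max(hyd$Q[, 1]) / base, 1000)
})

test_that("routing rejects misaligned grids and negative flows", {
  net <- default_network()
  bad <- data.frame(date = c(1, 2, 1), location = c("a", "a", "b"),
                    flow_m3s = 1)
  expect_error(route_flow(net, bad, c(a = 0, b = 0.8)), "time grid")
  expect_error(route_flow(net, cbind(spring = c(-1, 1),
                                     rc_upstream = c(1, 1)),
                          c(spring = 0, rc_upstream = 0.8)), "negative")
})

test_that("base-flow dilution of the tributary lies in the observed 5-10 range", {
  hyd <- steady_hydro(nd = 3)
  d <- dilution_factor(hyd)
  expect_equal(d, 8)
  expect_gte(d, 5); expect_lte(d, 10)
})
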