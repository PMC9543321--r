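test_that("rating concentration evaluates power law and first-order decay", {
  sp <- source_spec("s", "upstream_spring", mile = 0, a_base = 100,
                    b_base = 0, lambda = 0)
  expect_equal(rating_concentration(sp, c(0.01, 1, 100), 0),
               rep(100, 3))                              # constant source
  sp6 <- source_spec("s", "upstream_spring", mile = 0, a_base = 100,
                     lambda = 0.06)
  expect_equal(rating_concentration(sp6, sp6$q_ref, 6), 69.77,
               tolerance = 1e-4)                         # 6-yr survival 0.70a
  spb <- source_spec("s", "upstream_spring", mile = 0, a_base = 100,
                     b_base = 0.5, q_ref = 1, lambda = 0)
  expect_equal(rating_concentration(spb, 4, 0), 200)
  expect_error(rating_concentration(sp, 0, 0), "positive")
})

test_that("storm regime switches at the flow threshold", {
  sp <- source_spec("s", "upstream_spring", mile = 0, a_base = 100,
                    b_base = 0, a_storm = 150, b_storm = 0.3,
                    q_ref = 1, q_storm = 2, lambda = 0)
  expect_equal(rating_concentration(sp, 1.9, 0), 100)
  expect_equal(rating_concentration(sp, 4, 0), 150 * 4^0.3)
})

test_that("concentration is non-increasing in time at fixed flow when lambda > 0", {
  sp <- source_spec("s", "nsb_seep", mile = 0.2, a_base = 300, lambda = 0.04)
  tt <- seq(0, 20, by = 0.5)
  cc <- rating_concentration(sp, rep(sp$q_ref, length(tt)), tt)
  expect_true(all(diff(cc) < 0))
})

test_that("loads compile with correct unit arithmetic and attach to the right cell", {
  net <- default_network()
  sp <- source_spec("s", "stf_effluent", mile = 0.3, a_base = 100,
                    lambda = 0)
  L <- compile_loads(list(sp), net, flows = list(s = c(0.01, 0)),
                     dates = c(0, 1))
  cell <- mile_to_cell(net, 0.3)
  expect_equal(L$s[1, cell] / 1000, 86.4)   # 100 ng/L at 0.01 m3/s = 86.4 mg/d
  expect_equal(L$s[2, cell], 0)             # zero flow, zero load
  expect_equal(sum(L$s[, -cell]), 0)
  # superposition: two co-located sources add; doubling doubles
  L2 <- compile_loads(list(sp, source_spec("s2", "stf_effluent", mile = 0.3,
                                           a_base = 100, lambda = 0,
                                           flow_series_ref = "s")),
                      net, flows = list(s = c(0.01, 0)), dates = c(0, 1))
  expect_equal(L2$s + L2$s2, 2 * L$s)
})

test_that("decay-rate regression recovers lambda exactly on noise-free input", {
  tt <- seq(0, 5, length.out = 40)
  d <- data.frame(time = tt, conc = 120 * exp(-0.06 * tt))
  fit <- fit_decay_rate(d)
  expect_equal(fit$lambda, 0.06, tolerance = 1e-10)
  # with a flow covariate present and active
  q <- exp(sin(tt))
  d2 <- data.frame(time = tt, conc = 120 * q^0.3 * exp(-0.06 * tt), flow = q)
  expect_equal(fit_decay_rate(d2)$lambda, 0.06, tolerance = 1e-10)
  # constant series: zero decline
  expect_equal(fit_decay_rate(data.frame(time = tt, conc = 50))$lambda, 0)
})

test_that("decay regression enforces its preconditions", {
  tt <- seq(0, 5, length.out = 20)
  expect_error(fit_decay_rate(data.frame(time = tt[1:5], conc = 1:5)),
               "at least 8")
  expect_error(fit_decay_rate(data.frame(time = tt / 10, conc = tt + 1)),
               "2 years")
  expect_error(fit_decay_rate(data.frame(time = tt, conc = c(-1, tt[-1]))),
               "substitute nondetects")
})
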