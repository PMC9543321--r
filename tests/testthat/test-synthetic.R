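test_that("flow generation is seed-reproducible, positive and storm-scaled", {
  cfg <- synth_config()
  f1 <- gen_flows(cfg, seed = 1)
  f2 <- gen_flows(cfg, seed = 1)
  expect_identical(f1, f2)
  expect_false(identical(f1, gen_flows(cfg, seed = 2)))
  expect_true(all(f1$flow_m3s > 0))
  qs <- f1$flow_m3s[f1$location == "spring"]
  ratio <- max(qs) / cfg$spring$base_flow
  expect_gte(ratio, 100); expect_lte(ratio, 1000)   # three orders of magnitude
  qr <- f1$flow_m3s[f1$location == "rc_upstream"]
  expect_gte(max(qr) / cfg$rc$base_flow, 10)        # flashy, ~two orders
  # a quiescent configuration collapses to the constant base flow
  cfg0 <- synth_config(storms_per_year = 0)
  cfg0$spring$sigma_log <- 0; cfg0$rc$sigma_log <- 0
  f0 <- gen_flows(cfg0, seed = 1)
  expect_true(all(f0$flow_m3s[f0$location == "spring"] ==
                    cfg0$spring$base_flow))
})

test_that("spring concentrations follow the rating exactly when noise-free", {
  cfg <- synth_config(); cfg$obs_cv <- 0
  fl <- gen_flows(cfg, seed = 4)
  obs <- gen_spring_concentrations(cfg, fl, seed = 4)
  expect_equal(obs$conc, obs$conc_true)
  fit <- fit_decay_rate(data.frame(time = obs$date, conc = obs$conc,
                                   flow = obs$flow))
  expect_equal(fit$lambda, 0.06, tolerance = 1e-8)   # exact recovery
  expect_equal(nrow(obs), 60)                        # monthly over 5 years
})

test_that("fish composites average individuals and reduce variance threefold", {
  s <- gen_fish_samples(2, cv = 0, n_fish = 30, seed = 1)
  expect_equal(nrow(s), 10)                          # 30 fish, 10 analyses
  expect_equal(s$conc, rep(2, 10))
  expect_true(all(s$n_fish == 3))
  # Monte-Carlo: composite variance ~ individual variance / 3
  set.seed(7)
  sdlog <- sqrt(log(1 + 0.5^2))
  big <- gen_fish_samples(2, cv = 0.5, n_fish = 3 * 4000, seed = 7)
  v_ind <- (2 * 0.5)^2
  expect_equal(var(big$conc), v_ind / 3, tolerance = 0.1)
  expect_equal(mean(big$conc), 2, tolerance = 0.05)  # unbiased
  expect_error(gen_fish_samples(2, 0.5, n_fish = 31), "divisible")
})

test_that("the site fixture is complete, self-consistent and byte-stable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx <- gen_site_fixture(seed = 1, dir = d1)
  gen_site_fixture(seed = 1, dir = d2)
  files <- c("flows.csv", "spring_monitoring.csv", "fish_composites.csv",
             "site.yaml")
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # the written config round-trips through YAML
  cfg <- read_site_config(file.path(d1, "site.yaml"))
  expect_equal(network_miles(cfg$network), 3.0)
  expect_equal(cfg$spring$lambda, 0.06)
  expect_equal(cfg$species$creek_chub$k_u,
               default_species("creek_chub")$k_u)
  # the flow CSV feeds straight back into routing
  fl <- read_flows_csv(file.path(d1, "flows.csv"))
  hyd <- route_flow(cfg$network, fl,
                    c(spring = 0, rc_upstream = cfg$rc_upstream_mile))
  expect_true(all(hyd$Q > 0))
})

test_that("a zero-source fixture yields zero concentrations everywhere", {
  cfg <- default_site_config()
  cfg$spring$a_base <- 0; cfg$spring$a_storm <- 0
  cfg$nsb$a_base <- 0; cfg$nsb$a_storm <- 0
  cfg$bed_conc[] <- 0
  p <- run_projection(cfg, 2, "base", years = 1, seed = 2)
  expect_equal(max(p$water$cw), 0)
  expect_equal(max(vapply(p$fish, function(f) max(f$series$conc), 0)), 0)
})

test_that("an end-to-end fixture run recovers the configured decay rate", {
  fx <- gen_site_fixture(seed = 1)
  v <- substitute_nondetects(fx$spring_obs$conc, fx$spring_obs$detected,
                             fx$spring_obs$mdl)
  fit <- fit_decay_rate(data.frame(time = fx$spring_obs$date, conc = v,
                                   flow = fx$spring_obs$flow))
  expect_true(abs(fit$lambda - 0.06) < 2.5 * fit$se)
})
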