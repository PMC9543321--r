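flat_species <- function(k_u = 100, k_e = 0.015, weight_exp = 0,
                         diet = c(benthic = 0, water_column = 0,
                                  terrestrial = 1), ...) {
  species_params("flat", weight_coeff = 20, weight_exp = weight_exp,
                 lipid_by_month = rep(0.05, 12),
                 diet_by_month = matrix(diet, 12, 3, byrow = TRUE),
                 k_u = k_u, k_e = k_e, resp_theta = 0, ...)
}

const_exposure <- function(cw = 10, cbed = 0, nd = 1500) {
  list(dates = as.Date("2001-01-01") + 0:(nd - 1),
       cw_diss = rep(cw, nd), cbed = rep(cbed, nd), foc = 0.03)
}

test_that("prey compartments follow their equilibrium factors", {
  p <- invert_params(beta_soc = 1, baf_w = 1e5, lipid_benthic = 0.02,
                     lipid_water = 0.02)
  z <- invertebrate_concentrations(0, 0, foc = 0.04, p)
  expect_equal(unlist(z), c(benthic = 0, water_column = 0, terrestrial = 0))
  expect_equal(invertebrate_concentrations(0, 2, 0.04, p)$benthic, 1.0)
  expect_equal(invertebrate_concentrations(50, 0, 0.04, p)$water_column,
               1e5 * 50 * 1e-6 * 0.02)
  expect_equal(invertebrate_concentrations(1e4, 100, 0.04, p)$terrestrial, 0)
  expect_error(invertebrate_concentrations(0, 2, 0, p), "foc")
})

test_that("bioenergetics closure I = (R + G) / AE", {
  # constant weight: no growth
  sp0 <- flat_species(weight_exp = 0)
  expect_equal(bioenergetics_rates(20, 15, sp0)$G, 0)
  # R = 0.01, G = 0.005, AE = 0.8 -> I = 0.01875
  sp <- species_params("x", weight_coeff = 20,
                       weight_exp = 0.005 * 365.25,
                       lipid_by_month = rep(0.05, 12),
                       diet_by_month = matrix(c(0, 0, 1), 12, 3,
                                              byrow = TRUE),
                       k_u = 0, k_e = 0.01, resp_alpha = 0.01,
                       resp_gamma = 0, resp_theta = 0, AE = 0.8)
  r <- bioenergetics_rates(20, 15, sp)   # age 1 on the growth curve
  expect_equal(r$G, 0.005, tolerance = 1e-12)
  expect_equal(r$I, 0.01875, tolerance = 1e-12)
  # theta = 0: feeding independent of temperature
  expect_equal(bioenergetics_rates(20, 5, sp)$I,
               bioenergetics_rates(20, 25, sp)$I)
})

test_that("zero exposure depurates exponentially from the initial burden", {
  sp <- flat_species(k_e = 0.02)
  ex <- const_exposure(cw = 0, nd = 200)
  fs <- simulate_fish(ex, sp, nu0 = 4)
  co <- fs$cohorts[fs$cohorts$birth < ex$dates[1] &
                     fs$cohorts$age_class %in% 1:3, ]
  co <- co[co$cohort == co$cohort[1], ]
  t_d <- as.numeric(co$date - ex$dates[1]) + 1
  expect_equal(co$conc, 4 * exp(-0.02 * t_d), tolerance = 1e-8)
})

test_that("constant dissolved-only exposure reaches the closed-form steady state", {
  sp <- flat_species(k_u = 100, k_e = 0.015)
  fs <- simulate_fish(const_exposure(cw = 10), sp)
  nu_ss <- 100 * 10 * 1e-6 / 0.015                    # 0.0667 mg/kg
  expect_equal(utils::tail(fs$station_mean$conc, 1), nu_ss,
               tolerance = 0.01)
})

test_that("steady state is monotone in exposure, uptake and elimination", {
  ss <- function(ku = 100, ke = 0.015, cw = 10, cbed = 0) {
    sp <- flat_species(k_u = ku, k_e = ke,
                       diet = c(0.5, 0.2, 0.3))
    utils::tail(simulate_fish(const_exposure(cw, cbed), sp)$station_mean$conc,
                1)
  }
  base <- ss()
  expect_gt(ss(cw = 20), base)
  expect_gt(ss(cbed = 5), base)
  expect_gt(ss(ku = 200), base)
  expect_lt(ss(ke = 0.03), base)
})

test_that("seasonal lipid and diet produce within-year oscillation", {
  sp <- default_species("creek_chub")
  fs <- simulate_fish(const_exposure(cw = 50, cbed = 4, nd = 365 * 4), sp)
  yr <- format(fs$station_mean$date, "%Y") == "2003"
  osc <- max(fs$station_mean$conc[yr]) / min(fs$station_mean$conc[yr])
  expect_gt(osc, 1.05)
})

test_that("a larger terrestrial diet fraction strictly lowers the burden", {
  mk <- function(terr) flat_species(k_u = 0, k_e = 0.01,
                                    diet = c(0.9 - terr, 0.1, terr))
  ss <- vapply(c(0.1, 0.3, 0.6), function(tf)
    utils::tail(simulate_fish(const_exposure(cw = 0, cbed = 5),
                              mk(tf))$station_mean$conc, 1), 0)
  expect_true(all(diff(ss) < 0))
})

test_that("species parameter validation catches inconsistent inputs", {
  expect_error(flat_species(diet = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(species_params("x", 10, 1, rep(1.2, 12),
                              matrix(c(0, 0, 1), 12, 3, byrow = TRUE),
                              k_u = 1, k_e = 0.01), "lipid")
  expect_error(bioenergetics_rates(-5, 10, flat_species()), "positive")
})
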