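# All generators take an explicit seed, save and restore the caller's RNG
# state, and therefore have no hidden global state.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for reproducibility")
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Synthetic monitoring-record configuration
#'
#' Distributions for the synthetic site record: lognormal base flows with
#' Poisson-arriving storm pulses that decay exponentially over one to a few
#' days (the flashy karst-fed hydrograph), flow-rated spring PCB
#' concentrations declining at ~6 %/yr with lognormal observation error and
#' nondetect censoring, and fish composites of three individuals with
#' lognormal among-fish variability. Defaults reproduce the documented flow
#' regime: storm flows up to three orders of magnitude above base flow in
#' the upper stream and two orders in the receiving creek.
#'
#' @param years length of the record (default 5, the calibration span).
#' @param start_date first day.
#' @param spring,rc per-stream flow models: `base_flow` (m^3/s, the
#'   median), `sigma_log` (lognormal day-to-day spread), and a `storm`
#'   list (`meanlog`, `sdlog`, `min`, `max` multipliers and, for the
#'   spring, `tau_range` days of pulse decay).
#' @param storms_per_year Poisson storm arrival rate (events/yr, shared
#'   between the streams).
#' @param obs_cv lognormal coefficient of variation of water observations.
#' @param mdl method detection limit for water samples (ng/L).
#' @param fish_cv lognormal among-fish coefficient of variation.
#' @param composite_size fish per composite analysis (default 3).
#' @param samples_per_year water monitoring frequency (default monthly).
#' @param fish_true_mean named true station means (mg/kg) used by the
#'   fixture's fish monitoring tables.
#' @param fish_n named fish counts per station monitoring round.
#' @return class `"synth_config"`.
#' @export
synth_config <- function(years = 5, start_date = as.Date("2001-01-01"),
                         spring = list(base_flow = 0.06, sigma_log = 0.25,
                                       storm = list(meanlog = log(60),
                                                    sdlog = 1.0,
                                                    min = 5, max = 700,
                                                    tau_range = c(0.3, 1.2))),
                         rc = list(base_flow = 0.35, sigma_log = 0.25,
                                   storm = list(meanlog = log(15),
                                                sdlog = 0.8,
                                                min = 3, max = 90)),
                         storms_per_year = 22,
                         obs_cv = 0.5, mdl = 10,
                         fish_cv = 0.5, composite_size = 3,
                         samples_per_year = 12,
                         fish_true_mean = c(CBVP = 1.5, RCVP = 0.55,
                                            RC43 = 0.12),
                         fish_n = c(CBVP = 60, RCVP = 60, RC43 = 54)) {
  if (obs_cv < 0 || fish_cv < 0) stop("dispersions must be non-negative")
  structure(list(years = years, start_date = as.Date(start_date),
                 spring = spring, rc = rc,
                 storms_per_year = storms_per_year,
                 obs_cv = obs_cv, mdl = mdl, fish_cv = fish_cv,
                 composite_size = composite_size,
                 samples_per_year = samples_per_year,
                 fish_true_mean = fish_true_mean, fish_n = fish_n),
            class = "synth_config")
}

#' Generate synthetic boundary flows
#'
#' Daily flows for the spring inflow and the receiving-creek upstream
#' boundary: lognormal base flow times `(1 + sum of storm pulses)`. Storm
#' events arrive as a Poisson process shared between the streams (storms
#' are regional); each event draws one standard-normal deviate that scales
#' both streams' truncated-lognormal peak multipliers, and decays
#' exponentially over `tau` days.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return long data frame: `date`, `location` (`"spring"`,
#'   `"rc_upstream"`), `flow_m3s` (strictly positive).
#' @export
gen_flows <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(seed, {
    n <- round(cfg$years * 365.25)
    dates <- cfg$start_date + 0:(n - 1)
    base_of <- function(s) s$base_flow * exp(s$sigma_log * stats::rnorm(n))
    b_sp <- base_of(cfg$spring)
    b_rc <- base_of(cfg$rc)
    ne <- stats::rpois(1, cfg$storms_per_year * cfg$years)
    t0 <- sort(stats::runif(ne, 0, n))
    z <- stats::rnorm(ne)
    tau <- stats::runif(ne, cfg$spring$storm$tau_range[1],
                        cfg$spring$storm$tau_range[2])
    pulse <- function(storm) {
      mult <- pmin(pmax(exp(storm$meanlog + storm$sdlog * z), storm$min),
                   storm$max)
      p <- numeric(n)
      day <- seq_len(n)
      for (e in seq_len(ne)) {
        i <- which(day >= t0[e])
        p[i] <- p[i] + mult[e] * exp(-(day[i] - t0[e]) / tau[e])
      }
      p
    }
    q_sp <- b_sp * (1 + pulse(cfg$spring$storm))
    q_rc <- b_rc * (1 + pulse(cfg$rc$storm))
    rbind(data.frame(date = dates, location = "spring", flow_m3s = q_sp),
          data.frame(date = dates, location = "rc_upstream",
                     flow_m3s = q_rc))
  })
}

#' Generate a synthetic spring concentration monitoring series
#'
#' Samples the spring on a regular routine-monitoring schedule (grabs that
#' would fall on storm-regime days shift to the calmest day within ten
#' days, as routine grabs are collected under nonstorm conditions),
#' evaluates the flow rating with first-order decay, multiplies by
#' lognormal observation error (median-unbiased, so a log-linear fit on a
#' noise-free series recovers the decay rate exactly), and censors below
#' the detection limit.
#'
#' @param cfg a [synth_config()].
#' @param flows output of [gen_flows()] (the `"spring"` rows are used).
#' @param spec the spring [source_spec()]; defaults to the default site's.
#' @param seed integer seed.
#' @return data frame: `date`, `flow` (m^3/s), `conc_true`, `conc`
#'   (ng/L), `detected`, `mdl`.
#' @export
gen_spring_concentrations <- function(cfg, flows, spec = NULL, seed = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(spec)) {
    s <- default_site_config()$spring
    spec <- source_spec("spring", "upstream_spring", mile = s$mile,
                        a_base = s$a_base, b_base = s$b_base,
                        a_storm = s$a_storm, b_storm = s$b_storm,
                        q_ref = s$q_ref, q_storm = s$q_storm,
                        lambda = s$lambda)
  }
  sp <- flows[flows$location == "spring", ]
  n <- nrow(sp)
  per <- n / (cfg$years * cfg$samples_per_year)
  idx <- round(seq(per / 2, n - per / 2, length.out =
                     cfg$years * cfg$samples_per_year))
  # routine monitoring samples under nonstorm conditions: shift any
  # scheduled grab falling on a storm-regime day to the calmest day nearby
  q_th <- spec$q_storm
  idx <- vapply(idx, function(i) {
    if (sp$flow_m3s[i] <= q_th) return(i)
    win <- max(1, i - 10):min(n, i + 10)
    win[which.min(sp$flow_m3s[win])]
  }, numeric(1))
  .with_seed(seed, {
    q <- sp$flow_m3s[idx]
    d <- sp$date[idx]
    true <- rating_concentration(spec, q, d)
    sdlog <- sqrt(log(1 + cfg$obs_cv^2))
    obs <- true * exp(sdlog * stats::rnorm(length(idx)))
    data.frame(date = d, flow = q, conc_true = true, conc = obs,
               detected = obs >= cfg$mdl, mdl = cfg$mdl)
  })
}

#' Generate synthetic fish composite samples
#'
#' Individual fish concentrations are lognormal with the given arithmetic
#' mean and coefficient of variation; composites average
#' `composite_size` individuals, so the expected composite mean equals the
#' true mean and the composite variance is the individual variance divided
#' by the composite size.
#'
#' @param true_mean arithmetic mean tissue concentration (mg/kg).
#' @param cv among-fish coefficient of variation.
#' @param n_fish number of fish (must be divisible by `composite_size`).
#' @param composite_size fish per composite (default 3).
#' @param seed integer seed.
#' @param station,species,date,basis sample labels.
#' @return data frame of composite analyses: `station`, `species`,
#'   `date`, `n_fish`, `conc` (mg/kg), `basis`.
#' @export
gen_fish_samples <- function(true_mean, cv, n_fish, composite_size = 3,
                             seed = 1, station = "CBVP",
                             species = "creek_chub",
                             date = as.Date("2017-05-15"),
                             basis = "whole_body") {
  if (n_fish %% composite_size != 0)
    stop("n_fish must be divisible by composite_size")
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    indiv <- stats::rlnorm(n_fish, log(true_mean) - sdlog^2 / 2, sdlog)
    comp <- colMeans(matrix(indiv, nrow = composite_size))
    data.frame(station = station, species = species, date = date,
               n_fish = composite_size, conc = comp, basis = basis)
  })
}

#' Generate a complete synthetic site fixture
#'
#' A self-consistent small-site dataset on which the whole pipeline runs:
#' boundary flows, a spring monitoring table, and post-remedy fish
#' composite tables per station. With `dir` set, the fixture is written as
#' plain-text files (`flows.csv`, `spring_monitoring.csv`,
#' `fish_composites.csv`, `site.yaml`); regeneration with the same seed
#' reproduces the files byte for byte.
#'
#' @param config a site configuration (default [default_site_config()]).
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return (invisibly, when writing) list with `config`, `flows`,
#'   `spring_obs`, `fish_obs` and `dir`.
#' @export
gen_site_fixture <- function(config = default_site_config(), seed = 1,
                             dir = NULL) {
  cfg <- config
  flows <- gen_flows(cfg$synth, seed = seed)
  s <- cfg$spring
  spec <- source_spec("spring", "upstream_spring", mile = s$mile,
                      a_base = s$a_base, b_base = s$b_base,
                      a_storm = s$a_storm, b_storm = s$b_storm,
                      q_ref = s$q_ref, q_storm = s$q_storm,
                      lambda = s$lambda, t0 = cfg$t0)
  spring_obs <- gen_spring_concentrations(cfg$synth, flows, spec,
                                          seed = seed + 1)
  events <- as.Date(c("2017-05-15", "2017-11-15"))
  fish_obs <- do.call(rbind, lapply(names(cfg$stations), function(st) {
    stn <- cfg$stations[[st]]
    nf <- cfg$synth$fish_n[[st]] / length(events)
    do.call(rbind, lapply(seq_along(events), function(e)
      gen_fish_samples(cfg$synth$fish_true_mean[[st]], cfg$synth$fish_cv,
                       n_fish = nf,
                       composite_size = cfg$synth$composite_size,
                       seed = seed + 10 * e + match(st, names(cfg$stations)),
                       station = st, species = stn$species[1],
                       date = events[e], basis = stn$basis)))
  }))
  out <- list(config = cfg, flows = flows, spring_obs = spring_obs,
              fish_obs = fish_obs, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(flows, file.path(dir, "flows.csv"), row.names = FALSE)
    utils::write.csv(spring_obs, file.path(dir, "spring_monitoring.csv"),
                     row.names = FALSE)
    utils::write.csv(fish_obs, file.path(dir, "fish_composites.csv"),
                     row.names = FALSE)
    write_site_config(cfg, file.path(dir, "site.yaml"))
    return(invisible(out))
  }
  out
}
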