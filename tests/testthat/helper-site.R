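# Shared fixtures, built in code.

# steady two-reach hydrology (constant inflows, nd days)
steady_hydro <- function(net = default_network(), spring = 0.05,
                         rc = 0.35, nd = 30,
                         dates = as.Date("2001-01-01") + seq_len(nd) - 1) {
  fm <- cbind(spring = rep(spring, nd), rc_upstream = rep(rc, nd))
  route_flow(net, fm, c(spring = 0, rc_upstream = 0.8), dates = dates)
}

# a closed, well-mixed single cell with prescribed depth and no flow
closed_cell <- function(depth = 0.5, nd = 2, width = 2, dx_mile = 0.1,
                        dispersion = 0) {
  net <- reach_network(reach("X", 0, dx_mile, width = width, slope = 1e-3,
                             roughness = 0.05, n_cells = 1,
                             dispersion = dispersion))
  vol <- width * depth * miles_to_m(dx_mile)
  hyd <- structure(list(
    network = net, dates = seq_len(nd),
    Q = matrix(0, nd, 1), depth = matrix(depth, nd, 1),
    velocity = matrix(0, nd, 1), area = matrix(width * depth, nd, 1),
    volume = matrix(vol, nd, 1),
    inflow = matrix(0, nd, 1), inflow_cell = c(x = 1)),
    class = "hydro_series")
  list(network = net, hydro = hyd)
}

# a calibration-period-like loading set on the default network:
# rated spring at the weir, NSB seeps, constant effluent, storm-scaled TSS
calib_inputs <- function(years = 1, seed = 3, net = default_network()) {
  fl <- gen_flows(synth_config(years = years), seed = seed)
  qs <- fl$flow_m3s[fl$location == "spring"]
  qrc <- fl$flow_m3s[fl$location == "rc_upstream"]
  nd <- length(qs)
  dates <- as.Date("2001-01-01") + 0:(nd - 1)
  hydro <- route_flow(net, cbind(spring = qs, rc_upstream = qrc),
                      c(spring = 0, rc_upstream = 0.8), dates = dates)
  n <- nrow(net$cells)
  at <- function(mile, v) {
    m <- matrix(0, nd, n); m[, mile_to_cell(net, mile)] <- v; m
  }
  spec <- source_spec("spring", "upstream_spring", mile = 0, a_base = 250,
                      b_base = 0, a_storm = 250, b_storm = 0.25,
                      q_ref = 0.06, q_storm = 0.12, lambda = 0.06)
  cs <- rating_concentration(spec, qs, dates)
  loads <- list(
    spring = at(0, qs * 86400 * cs),
    nsb = at(0.2, 0.1 * qs * 86400 * 300),
    effluent = at(0.3, rep(gpm_to_m3s(450) * 86400 * 50, nd)))
  tss <- at(0, qs * 86400 * 4 * (qs / stats::median(qs))^0.7) +
    at(0.8, qrc * 86400 * 4 * (qrc / stats::median(qrc))^0.7)
  list(net = net, hydro = hydro, loads = loads, tss = tss,
       dates = dates, flows = fl)
}

# memoised long projections shared by the acceptance tests
.proj_cache <- new.env(parent = emptyenv())
cached_projection <- function(alt, calib, years = 10) {
  key <- paste0("a", alt, "_", calib, "_", years)
  if (is.null(.proj_cache[[key]])) {
    if (is.null(.proj_cache$flows))
      .proj_cache$flows <- gen_flows(default_site_config()$synth, seed = 1)
    .proj_cache[[key]] <- run_projection(
      default_site_config(), alternative = alt, calibration = calib,
      years = years, seed = 1, flows = .proj_cache$flows)
  }
  .proj_cache[[key]]
}
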