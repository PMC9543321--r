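#' Default site configuration
#'
#' The complete run configuration for the default desk-scale site: the
#' two-reach network, the three PCB sources (upstream springs with
#' flow-stratified rating and 6 %/yr first-order decline, treatment-plant
#' effluent, NSB seeps), treatment-facility settings (450 gpm, 85 % base
#' capture, 99 % removal), fate/transport and bed parameters, species and
#' monitoring stations with their compliance targets, and the synthetic
#' flow/monitoring generator settings. Channel geometry and the flow
#' regime follow the documented site description; rate constants the site
#' report did not publish are literature-plausible assumptions (see the
#' methods vignette).
#'
#' @return a list of class `"site_config"`.
#' @export
default_site_config <- function() {
  structure(list(
    network = default_network(),
    t0 = as.Date("2001-01-01"),
    spring = list(mile = 0.0, a_base = 250, b_base = 0,
                  a_storm = 250, b_storm = 0.25,
                  q_ref = 0.06, q_storm = 0.12, lambda = 0.06),
    nsb = list(mile = 0.20, a_base = 400, b_base = 0,
               a_storm = 400, b_storm = 0.2,
               q_ref = 0.006, q_storm = 0.012, lambda = 0.06,
               flow_frac = 0.10),
    stf = list(active = TRUE, capacity_gpm = 450, storage_gal = 0,
               capture_frac = 0.85, removal = 0.99, outfall_mile = 0.30),
    rc_upstream_mile = 0.8,
    tss = list(conc_base = 4, exponent = 0.7),
    fate = fate_params(),
    bed_conc = c(CB = 8, RC = 2),
    bed_foc = 0.03,
    dredge_residual = 1.0,
    nsb_captured = FALSE,
    nsb_load_factor = 1,
    storm_load_factor = 1,
    inverts = invert_params(),
    species = list(creek_chub = default_species("creek_chub"),
                   longear_sunfish = default_species("longear_sunfish")),
    stations = list(
      CBVP = list(mile = 0.74, species = "creek_chub",
                  basis = "whole_body", target = 2.3),
      RCVP = list(mile = 1.05,
                  species = c("creek_chub", "longear_sunfish"),
                  basis = "whole_body", target = 0.9),
      RC43 = list(mile = 2.95, species = "longear_sunfish",
                  basis = "fillet", target = 0.2)),
    fillet_ratio = 0.6,
    temperature = list(mean = 14, amplitude = 9, peak_doy = 205),
    floodplain_criterion_mgkg = 5,   # recorded; no floodplain model
    synth = synth_config()
  ), class = "site_config")
}

#' @export
print.site_config <- function(x, ...) {
  cat("<site_config> ", network_miles(x$network), " miles, sources: ",
      "spring (a=", x$spring$a_base, " ng/L, lambda=", x$spring$lambda,
      "/yr), NSB, STF effluent\n", sep = "")
  cat("  stations: ", paste(names(x$stations), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# ---- YAML round trip ------------------------------------------------------

#' Read and write site configurations as YAML
#'
#' The on-disk schema mirrors [default_site_config()]: a `network` block
#' (list of reaches with miles, width/slope/roughness in SI, cells,
#' dispersion), source blocks, `stf`, `fate`, bed, species (growth curve,
#' monthly lipid and diet vectors, kinetic rates), stations and `synth`
#' blocks. Dates are ISO-8601 strings.
#'
#' @param config a `"site_config"`.
#' @param path file path.
#' @return `read_site_config()` returns a `"site_config"`;
#'   `write_site_config()` returns the path invisibly.
#' @export
write_site_config <- function(config, path) {
  x <- config
  repr <- list(
    network = lapply(x$network$reaches, function(r)
      r[c("id", "start_mile", "end_mile", "width", "slope", "roughness",
          "n_cells", "dispersion")]),
    t0 = as.character(x$t0),
    spring = x$spring, nsb = x$nsb, stf = x$stf,
    rc_upstream_mile = x$rc_upstream_mile, tss = x$tss,
    fate = unclass(x$fate),
    bed_conc = as.list(x$bed_conc), bed_foc = x$bed_foc,
    dredge_residual = x$dredge_residual,
    nsb_captured = x$nsb_captured,
    nsb_load_factor = x$nsb_load_factor,
    storm_load_factor = x$storm_load_factor,
    inverts = unclass(x$inverts),
    species = lapply(x$species, function(sp) list(
      name = sp$name, weight_coeff = sp$weight_coeff,
      weight_exp = sp$weight_exp,
      lipid_by_month = sp$lipid_by_month,
      diet_benthic = unname(sp$diet_by_month[, "benthic"]),
      diet_water_column = unname(sp$diet_by_month[, "water_column"]),
      diet_terrestrial = unname(sp$diet_by_month[, "terrestrial"]),
      k_u = sp$k_u, k_e = sp$k_e, alpha_d = sp$alpha_d,
      resp_alpha = sp$resp_alpha, resp_gamma = sp$resp_gamma,
      resp_theta = sp$resp_theta, AE = sp$AE,
      age_classes = sp$age_classes, birthday = sp$birthday)),
    stations = x$stations, fillet_ratio = x$fillet_ratio,
    temperature = x$temperature,
    floodplain_criterion_mgkg = x$floodplain_criterion_mgkg,
    synth = c(unclass(x$synth)[setdiff(names(unclass(x$synth)),
                                       c("start_date", "fish_true_mean",
                                         "fish_n"))],
              list(start_date = as.character(x$synth$start_date),
                   fish_true_mean = as.list(x$synth$fish_true_mean),
                   fish_n = as.list(x$synth$fish_n))))
  writeLines(yaml::as.yaml(repr, precision = 12), path)
  invisible(path)
}

#' @rdname write_site_config
#' @export
read_site_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_site_config()
  cfg$network <- reach_network(lapply(y$network, function(r)
    reach(r$id, r$start_mile, r$end_mile, r$width, r$slope, r$roughness,
          r$n_cells, r$dispersion)))
  cfg$t0 <- as.Date(y$t0)
  for (f in c("spring", "nsb", "stf", "rc_upstream_mile", "tss",
              "bed_foc", "dredge_residual", "nsb_captured",
              "nsb_load_factor", "storm_load_factor", "stations",
              "fillet_ratio", "temperature", "floodplain_criterion_mgkg"))
    cfg[[f]] <- y[[f]]
  cfg$bed_conc <- unlist(y$bed_conc)
  cfg$fate <- do.call(fate_params, y$fate)
  cfg$inverts <- do.call(invert_params, y$inverts)
  cfg$species <- lapply(y$species, function(sp)
    species_params(sp$name, sp$weight_coeff, sp$weight_exp,
                   unlist(sp$lipid_by_month),
                   cbind(benthic = unlist(sp$diet_benthic),
                         water_column = unlist(sp$diet_water_column),
                         terrestrial = unlist(sp$diet_terrestrial)),
                   k_u = sp$k_u, k_e = sp$k_e, alpha_d = sp$alpha_d,
                   resp_alpha = sp$resp_alpha, resp_gamma = sp$resp_gamma,
                   resp_theta = sp$resp_theta, AE = sp$AE,
                   age_classes = unlist(sp$age_classes),
                   birthday = sp$birthday))
  sy <- y$synth
  cfg$synth <- synth_config(
    years = sy$years, start_date = as.Date(sy$start_date),
    spring = sy$spring, rc = sy$rc, storms_per_year = sy$storms_per_year,
    obs_cv = sy$obs_cv, mdl = sy$mdl, fish_cv = sy$fish_cv,
    composite_size = sy$composite_size,
    samples_per_year = sy$samples_per_year,
    fish_true_mean = unlist(sy$fish_true_mean),
    fish_n = unlist(sy$fish_n))
  cfg
}

#' Read a boundary-flow CSV
#'
#' Expected columns: `date` (ISO-8601), `location`, `flow_m3s`.
#' @param path file path.
#' @return data frame suitable for [route_flow()] and [run_projection()].
#' @export
read_flows_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "location", "flow_m3s")
  if (!all(need %in% names(df)))
    stop("flow CSV needs columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  df
}

#' Write tidy fate/transport results and the mass-budget report
#'
#' @param fate a `"fate_result"`.
#' @param network the `reach_network` it was computed on.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the tidy data frame.
#' @export
write_fate_results <- function(fate, network, csv_path = NULL,
                               json_path = NULL) {
  cells <- network$cells
  nd <- nrow(fate$cw)
  df <- data.frame(
    date = rep(fate$dates, times = ncol(fate$cw)),
    cell = rep(cells$cell, each = nd),
    mile = rep(cells$mile_mid, each = nd),
    tss_mgL = as.vector(fate$tss),
    cw_ngL = as.vector(fate$cw),
    fd = as.vector(fate$fd),
    bed_mgkg = as.vector(fate$bed_active))
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(fate$budget, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(df)
}
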