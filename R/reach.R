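#' Define a stream reach
#'
#' A reach is a stretch of channel with uniform rectangular geometry on the
#' river-mile axis (mile 0 = the Conard's Branch weir, increasing
#' downstream). Reaches are discretized into equal-length cells for the
#' transport calculations.
#'
#' @param id character label, e.g. `"CB"`.
#' @param start_mile,end_mile river-mile coordinates; `end_mile > start_mile`.
#' @param width channel width (m).
#' @param slope dimensionless bed slope.
#' @param roughness Manning coefficient n (s m^-1/3).
#' @param n_cells number of equal-length cells (default 20).
#' @param dispersion longitudinal dispersion coefficient (m^2/s).
#' @return an object of class `"reach"`.
#' @seealso [reach_network()]
#' @export
#' @examples
#' reach("CB", 0, 0.8, width = ft_to_m(6), slope = 0.001, roughness = 0.06)
reach <- function(id, start_mile, end_mile, width, slope, roughness,
                  n_cells = 20, dispersion = 1) {
  stopifnot(is.character(id), length(id) == 1)
  if (!(end_mile > start_mile)) stop("end_mile must exceed start_mile")
  if (width <= 0 || slope <= 0 || roughness <= 0 || dispersion < 0)
    stop("width, slope and roughness must be positive; dispersion non-negative")
  n_cells <- as.integer(n_cells)
  if (n_cells < 1) stop("n_cells must be a positive integer")
  structure(
    list(id = id, start_mile = start_mile, end_mile = end_mile,
         width = width, slope = slope, roughness = roughness,
         n_cells = n_cells, dispersion = dispersion),
    class = "reach")
}

#' Assemble reaches into a network
#'
#' Reaches are chained upstream to downstream; each reach must begin where
#' the previous one ends. The default site network is the 0.8-mile Conard's
#' Branch joining the 2.2-mile modelled stretch of Richland Creek, 3.0 miles
#' in total.
#'
#' @param ... `reach` objects ordered upstream to downstream.
#' @return an object of class `"reach_network"` with a `cells` data frame
#'   (one row per cell: reach id, cell index, mile bounds, length `dx_m`,
#'   geometry, dispersion).
#' @export
#' @examples
#' net <- default_network()
#' network_miles(net)  # 3.0
reach_network <- function(...) {
  reaches <- list(...)
  if (length(reaches) == 1 && is.list(reaches[[1]]) &&
      !inherits(reaches[[1]], "reach")) reaches <- reaches[[1]]
  if (!length(reaches) || !all(vapply(reaches, inherits, TRUE, "reach")))
    stop("reach_network() takes one or more reach objects")
  for (k in seq_along(reaches)[-1]) {
    if (abs(reaches[[k]]$start_mile - reaches[[k - 1]]$end_mile) > 1e-9)
      stop("reaches must be contiguous upstream to downstream")
  }
  cells <- do.call(rbind, lapply(reaches, function(r) {
    edges <- seq(r$start_mile, r$end_mile, length.out = r$n_cells + 1)
    data.frame(
      reach = r$id,
      cell_in_reach = seq_len(r$n_cells),
      mile_lo = edges[-length(edges)],
      mile_hi = edges[-1],
      mile_mid = (edges[-1] + edges[-length(edges)]) / 2,
      dx_m = miles_to_m(diff(edges)),
      width = r$width, slope = r$slope, roughness = r$roughness,
      dispersion = r$dispersion,
      stringsAsFactors = FALSE)
  }))
  cells$cell <- seq_len(nrow(cells))
  rownames(cells) <- NULL
  structure(list(reaches = reaches, cells = cells),
            class = "reach_network")
}

#' @export
print.reach_network <- function(x, ...) {
  cat("<reach_network> ", length(x$reaches), " reaches, ",
      nrow(x$cells), " cells, ", format(network_miles(x)),
      " miles total\n", sep = "")
  for (r in x$reaches)
    cat(sprintf("  %s: mile %.2f-%.2f  w=%.2f m  S=%.4g  n=%.3f  E=%.2f m2/s  (%d cells)\n",
                r$id, r$start_mile, r$end_mile, r$width, r$slope,
                r$roughness, r$dispersion, r$n_cells))
  invisible(x)
}

#' Total network length in miles
#' @param network a `reach_network`.
#' @return numeric, total river miles spanned.
#' @export
network_miles <- function(network) {
  stopifnot(inherits(network, "reach_network"))
  sum(vapply(network$reaches, function(r) r$end_mile - r$start_mile, 0))
}

#' Map a river mile to its cell index
#' @param network a `reach_network`.
#' @param mile numeric vector of river miles.
#' @return integer cell indices.
#' @export
mile_to_cell <- function(network, mile) {
  cells <- network$cells
  lo <- min(cells$mile_lo); hi <- max(cells$mile_hi)
  if (any(mile < lo - 1e-9 | mile > hi + 1e-9))
    stop("mile outside the model domain [", lo, ", ", hi, "]")
  vapply(mile, function(m) {
    i <- which(m >= cells$mile_lo - 1e-9 & m < cells$mile_hi)
    if (!length(i)) i <- nrow(cells)  # downstream end
    i[1]
  }, integer(1))
}

#' Default two-reach site network
#'
#' Conard's Branch (mile 0 to 0.8; ~6 ft wide) joining Richland Creek
#' (mile 0.8 to 3.0; ~15 ft wide). Slopes and Manning coefficients are
#' chosen so the Manning stage-discharge rating reproduces the observed
#' base-flow depths (~0.6 ft and ~0.9 ft) at the default base flows;
#' dispersion coefficients are assumptions (no published dye-test values).
#'
#' @param n_cells cells per reach (default 20).
#' @return a `reach_network`.
#' @export
default_network <- function(n_cells = 20) {
  reach_network(
    reach("CB", 0.0, 0.8, width = ft_to_m(6), slope = 0.001,
          roughness = 0.060, n_cells = n_cells, dispersion = 0.5),
    reach("RC", 0.8, 3.0, width = ft_to_m(15), slope = 0.0017,
          roughness = 0.050, n_cells = n_cells, dispersion = 1.0))
}
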