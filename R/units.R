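# Internal unit system: SI for water (m, m3/s, s), field-customary for
# chemistry -- water-column PCBs in ng/L (numerically equal to ug/m3),
# sediment-bed PCBs in mg/kg dry weight, exchange velocities in m/d,
# PCB loads in ug/d, solids in mg/L (g/m3) and g/d.

#' Unit conversion constants and helpers
#'
#' Configuration files may describe the site in the customary US units the
#' monitoring record uses (feet, miles, gallons per minute, cubic feet per
#' second). These helpers convert to the SI units used internally.
#'
#' Constants: 1 ft = 0.3048 m; 1 mile = 1609.344 m; 1 gpm = 6.30902e-5 m3/s;
#' 1 cfs = 0.0283168 m3/s; 1 US gallon = 3.785412e-3 m3.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in SI units.
#' @examples
#' ft_to_m(6)        # Conard's Branch width
#' gpm_to_m3s(450)   # spring treatment facility capacity
#' @name units
NULL

#' @rdname units
#' @export
ft_to_m <- function(x) x * 0.3048

#' @rdname units
#' @export
miles_to_m <- function(x) x * 1609.344

#' @rdname units
#' @export
gpm_to_m3s <- function(x) x * 6.30902e-5

#' @rdname units
#' @export
cfs_to_m3s <- function(x) x * 0.0283168

#' @rdname units
#' @export
gallons_to_m3 <- function(x) x * 3.785412e-3

SEC_PER_DAY <- 86400
DAYS_PER_YEAR <- 365.25
RHO_WATER <- 1000   # kg/m3
GRAV <- 9.80665     # m/s2
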