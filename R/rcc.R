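#' Substitute nondetect values
#'
#' Nondetects are set to one-half the method detection limit; detected
#' values pass through unchanged.
#'
#' @param values measured concentrations (may be `NA` for nondetects).
#' @param detected logical vector.
#' @param mdl method detection limit(s), scalar or per sample; required
#'   (and positive) wherever `detected` is `FALSE`.
#' @return numeric vector.
#' @export
#' @examples
#' substitute_nondetects(c(0.42, NA), c(TRUE, FALSE), mdl = 0.10)
substitute_nondetects <- function(values, detected, mdl) {
  mdl <- rep_len(mdl, length(values))
  nd <- !detected
  if (any(nd & (is.na(mdl) | mdl <= 0)))
    stop("every nondetect needs a positive MDL")
  values[nd] <- mdl[nd] / 2
  values
}

#' Summarize composite analyses
#'
#' Arithmetic mean, standard error of the mean, and the mean +/- 2 SEM
#' interval. The statistical unit is the composite laboratory analysis,
#' not the individual fish (a composite of three fish is one observation).
#'
#' @param x numeric vector of composite concentrations, or a data frame
#'   with a `conc` column.
#' @return list: `n`, `mean`, `sd`, `sem`, `interval` (mean +/- 2 SEM),
#'   and `interval_defined` (`FALSE` with a warning when `n < 2`).
#' @export
#' @examples
#' summarize_composites(c(2, 4, 6))  # mean 4, SEM 1.1547
summarize_composites <- function(x) {
  if (is.data.frame(x)) x <- x$conc
  n <- length(x)
  m <- mean(x)
  if (n < 2) {
    warning("fewer than 2 analyses: SEM and interval undefined")
    return(list(n = n, mean = m, sd = NA_real_, sem = NA_real_,
                interval = c(NA_real_, NA_real_),
                interval_defined = FALSE))
  }
  s <- stats::sd(x)
  sem <- s / sqrt(n)
  list(n = n, mean = m, sd = s, sem = sem,
       interval = c(m - 2 * sem, m + 2 * sem), interval_defined = TRUE)
}

#' Remedy-confirmation specification
#'
#' Station fish-tissue targets, tissue basis, test level and review
#' interval for the compliance clause: 2.3 mg/kg whole-body at the upper
#' station (CBVP), 0.9 mg/kg whole-body at the receiving-creek station
#' (RCVP), 0.2 mg/kg fillet at the downstream bridge station (RC43),
#' tested at alpha = 0.05 every five years.
#'
#' @param targets named station targets (mg/kg).
#' @param basis named tissue basis per station.
#' @param alpha test level in (0, 1).
#' @param review_interval_yr years between reviews.
#' @param species_mix informational station species-mix rules.
#' @return class `"rcc_spec"`.
#' @export
rcc_spec <- function(targets = c(CBVP = 2.3, RCVP = 0.9, RC43 = 0.2),
                     basis = c(CBVP = "whole_body", RCVP = "whole_body",
                               RC43 = "fillet"),
                     alpha = 0.05, review_interval_yr = 5,
                     species_mix = list(
                       CBVP = "100% creek chub",
                       RCVP = "equal thirds top predators / omnivores / bottom feeders",
                       RC43 = "75% top predators, 25% bottom feeders")) {
  if (any(targets <= 0)) stop("targets must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(targets = targets, basis = basis, alpha = alpha,
                 review_interval_yr = review_interval_yr,
                 species_mix = species_mix),
            class = "rcc_spec")
}

#' Remedy-confirmation statistical test
#'
#' One-sample Student's t machinery against the station target with a
#' three-outcome decision: *success* when the mean is below the target by
#' a statistically significant margin (one-sided p for mu < target below
#' alpha), *failure* when it is above by a significant margin, and
#' *inconclusive* otherwise. The t statistic, SEM and p-values are
#' computed directly (mean, sample SD, `pt`), so a reference
#' implementation can serve as an independent check.
#'
#' @param samples numeric vector of composite concentrations (mg/kg), or
#'   a data frame with `conc` and optionally `basis` columns. At least 3
#'   composites are required.
#' @param spec an [rcc_spec()].
#' @param station station name (must be in the spec).
#' @param basis tissue basis of the samples; a mismatch with the station's
#'   target basis is an error, not a silent conversion.
#' @return class `"rcc_decision"`: `outcome`, `mean`, `sem`,
#'   `t_statistic`, `p_below`, `p_above`, `p_value` (the p-value of the
#'   achieved-target test, mu < target), `n`, `target`, `station`.
#' @export
#' @examples
#' sp <- rcc_spec()
#' rcc_test(c(1.0, 1.2, 0.8, 1.1, 0.9), sp, "CBVP")  # success
rcc_test <- function(samples, spec, station, basis = NULL) {
  stopifnot(inherits(spec, "rcc_spec"))
  if (!station %in% names(spec$targets)) stop("unknown station: ", station)
  if (is.data.frame(samples)) {
    if (is.null(basis) && !is.null(samples$basis))
      basis <- unique(samples$basis)
    samples <- samples$conc
  }
  if (!is.null(basis)) {
    if (length(basis) != 1 || !identical(basis, unname(spec$basis[station])))
      stop("sample basis (", paste(basis, collapse = "/"),
           ") does not match the ", station, " target basis (",
           spec$basis[station], ")")
  }
  n <- length(samples)
  if (n < 3) stop("at least 3 composite analyses are required")
  target <- spec$targets[[station]]
  m <- mean(samples)
  sem <- stats::sd(samples) / sqrt(n)
  t_stat <- (m - target) / sem
  p_below <- stats::pt(t_stat, df = n - 1)
  p_above <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  outcome <- if (p_below < spec$alpha) "success"
             else if (p_above < spec$alpha) "failure"
             else "inconclusive"
  structure(list(outcome = outcome, mean = m, sem = sem,
                 t_statistic = t_stat, p_below = p_below,
                 p_above = p_above, p_value = p_below, n = n,
                 target = target, station = station, alpha = spec$alpha),
            class = "rcc_decision")
}

#' @export
print.rcc_decision <- function(x, ...) {
  cat(sprintf(
    "<rcc_decision> %s at %s: mean %.3f vs target %.2f mg/kg (n=%d)\n",
    toupper(x$outcome), x$station, x$mean, x$target, x$n))
  cat(sprintf("  t = %.3f (df %d), p[mu<target] = %.3g, p[mu>target] = %.3g\n",
              x$t_statistic, x$n - 1, x$p_below, x$p_above))
  invisible(x)
}

#' Pre/post-remedy decline test
#'
#' One-sided Welch two-sample t-test of whether post-remedy concentrations
#' declined from pre-remedy concentrations (H1: post < pre), via
#' [stats::t.test()].
#'
#' @param pre,post numeric vectors (each n >= 2).
#' @param alpha test level.
#' @return list: `t`, `df`, `p`, `significant`.
#' @export
decline_test <- function(pre, post, alpha = 0.05) {
  if (length(pre) < 2 || length(post) < 2)
    stop("both groups need at least 2 observations")
  ht <- stats::t.test(post, pre, alternative = "less", var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha)
}
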