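#' Distribution of deleterious fitness effects (DDFE)
#'
#' Construct a validated DDFE specification. Three families are supported:
#' a log-normal parameterized by the median selection coefficient and the
#' standard deviation of `ln s`, a gamma parameterized by shape and mean,
#' and a degenerate point mass (useful for closed-form checks). Selection
#' coefficients `s` act against homozygotes; heterozygous effects are
#' `s * dominance_h`. On the X chromosome selection coefficients are scaled
#' by `chromosome_scale = 2/3` (genic selection, equal sex ratio).
#'
#' Mass above `s = 1` (possible under a heavy-tailed log-normal) is treated
#' as lethal and clamped to `s = 1` inside downstream integrals; the CDF
#' itself is left untouched.
#'
#' @param family one of `"lognormal"`, `"gamma"`, `"point_mass"`.
#' @param median_s median selection coefficient (log-normal family).
#' @param sd_log standard deviation of `ln s`, natural log (log-normal).
#' @param shape_k gamma shape parameter.
#' @param mean_s mean selection coefficient (gamma and point-mass families).
#' @param dominance_h dominance coefficient in `[0, 1]`; default 0.5.
#' @param chromosome_scale multiplicative factor on `s`: 1 for autosomes,
#'   `2/3` for the X chromosome.
#' @return an object of class `"ddfe"`.
#' @examples
#' ddfe("lognormal", median_s = 2.31e-4, sd_log = 5.308)
#' ddfe("gamma", shape_k = 0.3, mean_s = 2.5e-3)
#' @export
ddfe <- function(family = c("lognormal", "gamma", "point_mass"),
                 median_s = NULL, sd_log = NULL, shape_k = NULL,
                 mean_s = NULL, dominance_h = 0.5, chromosome_scale = 1) {
  family <- match.arg(family)
  if (!is.numeric(dominance_h) || dominance_h < 0 || dominance_h > 1)
    stop("dominance_h must lie in [0, 1]")
  if (!chromosome_scale %in% c(1, 2 / 3))
    stop("chromosome_scale must be 1 (autosome) or 2/3 (X)")
  chk <- function(x, nm) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("parameter '%s' must be a single positive number for family '%s'",
                   nm, family))
    x
  }
  params <- switch(family,
    lognormal = list(median_s = chk(median_s, "median_s"),
                     sd_log   = chk(sd_log, "sd_log")),
    gamma     = list(shape_k = chk(shape_k, "shape_k"),
                     mean_s  = chk(mean_s, "mean_s")),
    point_mass = list(mean_s = chk(mean_s, "mean_s")))
  structure(list(family = family, params = params, dominance_h = dominance_h,
                 chromosome_scale = chromosome_scale),
            class = "ddfe")
}

#' @export
print.ddfe <- function(x, ...) {
  p <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
             collapse = ", ")
  cat(sprintf("DDFE [%s] %s; h = %g; chromosome scale = %s\n",
              x$family, p, x$dominance_h,
              if (x$chromosome_scale == 1) "1 (autosome)" else "2/3 (X)"))
  invisible(x)
}

## CDF of the (chromosome-scaled) selection coefficient.
ddfe_cdf <- function(spec, s) {
  sc <- spec$chromosome_scale
  p <- spec$params
  switch(spec$family,
    lognormal = stats::plnorm(s, meanlog = log(p$median_s * sc), sdlog = p$sd_log),
    gamma     = stats::pgamma(s, shape = p$shape_k,
                              scale = p$mean_s * sc / p$shape_k),
    point_mass = as.numeric(s >= p$mean_s * sc))
}

## Density on the ln(s) scale of the scaled coefficient (continuous families).
ddfe_log_density <- function(spec, log_s) {
  sc <- spec$chromosome_scale
  p <- spec$params
  switch(spec$family,
    lognormal = stats::dnorm(log_s, mean = log(p$median_s * sc), sd = p$sd_log),
    gamma = {
      s <- exp(log_s)
      s * stats::dgamma(s, shape = p$shape_k, scale = p$mean_s * sc / p$shape_k)
    },
    stop("point_mass has no continuous density"))
}

#' Effectively-neutral truncation threshold
#'
#' The selection-coefficient threshold `s_T` below which mutations are
#' effectively neutral and excluded from the BGS computation. Autosomes use
#' `s_T = 1/Ne`. For the X chromosome, drift acts with `N_eX = 0.75 Ne` and
#' the threshold on the scale at which selection acts satisfies
#' `N_eX * s_X ~ 1`, i.e. `s_T = 1/(0.75 Ne)`.
#'
#' @param Ne effective population size (diploid individuals).
#' @param chromosome `"autosome"` or `"X"`.
#' @return object of class `"neutral_threshold"` with fields `Ne` and `s_T`.
#' @export
neutral_threshold <- function(Ne = 1e6, chromosome = c("autosome", "X")) {
  chromosome <- match.arg(chromosome)
  if (!is.numeric(Ne) || Ne <= 0) stop("Ne must be positive")
  s_T <- if (chromosome == "autosome") 1 / Ne else 1 / (0.75 * Ne)
  structure(list(Ne = Ne, chromosome = chromosome, s_T = s_T),
            class = "neutral_threshold")
}

#' Fraction of deleterious mutations that are effectively neutral
#'
#' Cumulative probability of the (chromosome-scaled) DDFE below the
#' truncation threshold `s_T`. These mutations contribute no background
#' selection; the complementary fraction rescales the deleterious mutation
#' rate (see [effective_deleterious_rate()]).
#'
#' @param spec a [ddfe()] object.
#' @param threshold a [neutral_threshold()] object, or a bare numeric `s_T`.
#' @return fraction in `[0, 1]`.
#' @examples
#' ln <- ddfe("lognormal", median_s = 2.31e-4, sd_log = 5.308)
#' neutral_fraction(ln, neutral_threshold(1e6))   # ~0.153
#' @export
neutral_fraction <- function(spec, threshold) {
  stopifnot(inherits(spec, "ddfe"))
  s_T <- if (inherits(threshold, "neutral_threshold")) threshold$s_T
         else as.numeric(threshold)
  if (length(s_T) != 1L || !is.finite(s_T) || s_T < 0)
    stop("threshold must be a single nonnegative number")
  if (s_T == 0) return(0)
  ddfe_cdf(spec, s_T)
}

#' Deleterious mutation rate relevant for BGS
#'
#' Multiplies a total deleterious rate by the fraction of mutations with
#' `s >= s_T`, the only ones that generate background selection.
#'
#' @param u_total per-bp per-haploid-copy per-generation deleterious rate.
#' @inheritParams neutral_fraction
#' @return rate per bp (same units as `u_total`).
#' @export
effective_deleterious_rate <- function(u_total, spec, threshold) {
  if (!is.numeric(u_total) || any(u_total < 0))
    stop("u_total must be nonnegative")
  u_total * (1 - neutral_fraction(spec, threshold))
}

#' TE deleterious insertion rate from mutation-selection balance
#'
#' For strongly deleterious, non-recessive insertions, mutation-selection
#' balance gives a segregation probability `P_seg = q * n`, so the per-bp
#' insertion rate is recovered as `u_TE = q * s_h` with
#' `q = P_seg / n_chromosomes_sampled`.
#'
#' @param n_exonic_tes number of TE insertions observed within exons.
#' @param exonic_bp exonic base pairs surveyed.
#' @param n_chromosomes_sampled chromosomes in the survey panel (default 15,
#'   the DSPR founder haplotypes).
#' @param s_h heterozygous selection coefficient against an exonic insertion.
#' @return list with `P_seg` (per bp), `q` (equilibrium frequency) and
#'   `u_te` (per bp per generation).
#' @examples
#' te_insertion_rate(633, 21e6, 15, 0.0025)  # u_te = 5e-9
#' @export
te_insertion_rate <- function(n_exonic_tes, exonic_bp,
                              n_chromosomes_sampled = 15, s_h = 0.0025) {
  if (exonic_bp <= 0) stop("exonic_bp must be positive")
  if (n_chromosomes_sampled <= 0) stop("n_chromosomes_sampled must be positive")
  if (s_h <= 0) stop("s_h must be positive")
  if (n_exonic_tes < 0) stop("n_exonic_tes must be nonnegative")
  P_seg <- n_exonic_tes / exonic_bp
  q <- P_seg / n_chromosomes_sampled
  list(P_seg = P_seg, q = q, u_te = q * s_h)
}
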