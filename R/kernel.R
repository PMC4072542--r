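## Inner BGS integrand: contribution of a selected site with homozygous
## coefficient s (heterozygous effect t = s*h) at recombination frequency r:
##   g(s, r) = t / (t + r (1 - t))^2
## At r = 0 this is 1/t, the classical fully-linked load term.
bgs_g <- function(s, h, r) {
  t <- s * h
  t / (t + r * (1 - t))^2
}

#' Precompute the BGS exponent kernel over a recombination grid
#'
#' Evaluates `K(r) = E[ g(s, r) ]` where the expectation is over the DDFE
#' truncated at `s_T` and renormalized, with lethal clamping of mass above
#' `s = 1`, and `g(s, r) = s h / (s h + r (1 - s h))^2`. Values are
#' computed by adaptive quadrature on the log-`s` scale at `n_grid`
#' log-spaced points spanning `[1e-10, 1]`, plus the exact `r = 0` value;
#' evaluation elsewhere interpolates linearly in `(ln r, ln K)`.
#'
#' @param spec a [ddfe()] object.
#' @param threshold a [neutral_threshold()] or numeric `s_T`.
#' @param n_grid number of grid points (>= 200; default 512).
#' @param r_min,r_max grid extent (defaults 1e-10 and 1).
#' @return object of class `"bgs_kernel"`.
#' @export
build_kernel <- function(spec, threshold, n_grid = 512,
                         r_min = 1e-10, r_max = 1) {
  stopifnot(inherits(spec, "ddfe"))
  if (n_grid < 200) stop("n_grid must be at least 200")
  s_T <- if (inherits(threshold, "neutral_threshold")) threshold$s_T
         else as.numeric(threshold)
  if (s_T <= 0) stop("truncation threshold s_T must be positive")
  h <- spec$dominance_h
  r_grid <- exp(seq(log(r_min), log(r_max), length.out = n_grid))

  if (spec$family == "point_mass") {
    s0 <- min(spec$params$mean_s * spec$chromosome_scale, 1)
    if (s0 < s_T)
      stop("point mass below the neutral threshold: kernel undefined")
    vals <- bgs_g(s0, h, r_grid)
    k0 <- 1 / (s0 * h)
  } else {
    trunc_mass <- 1 - ddfe_cdf(spec, s_T)
    if (trunc_mass <= 0)
      stop("no DDFE mass above the neutral threshold")
    lethal <- 1 - ddfe_cdf(spec, 1)          # mass clamped to s = 1
    kern_at <- function(r) {
      body <- tryCatch(
        stats::integrate(function(x) ddfe_log_density(spec, x) *
                           bgs_g(exp(x), h, r),
                         lower = log(s_T), upper = 0,
                         rel.tol = 1e-9, subdivisions = 2000L)$value,
        error = function(e) stop("kernel quadrature failed at r = ", r,
                                 ": ", conditionMessage(e)))
      (body + lethal * bgs_g(1, h, r)) / trunc_mass
    }
    vals <- vapply(r_grid, kern_at, numeric(1))
    k0 <- kern_at(0)
  }
  structure(list(r_grid = r_grid, values = vals, k0 = k0,
                 s_T = s_T, family = spec$family, h = h,
                 chromosome_scale = spec$chromosome_scale),
            class = "bgs_kernel")
}

#' Evaluate a precomputed kernel at arbitrary recombination frequencies
#'
#' `r <= 1e-10` (the fully-linked floor) returns the exact `r = 0` value;
#' otherwise linear interpolation in `(ln r, ln K)`.
#'
#' @param kernel a [build_kernel()] result.
#' @param r recombination frequencies in `[0, 1]` (vectorized).
#' @return kernel values.
#' @export
kernel_eval <- function(kernel, r) {
  out <- numeric(length(r))
  lo <- r <= kernel$r_grid[1]
  out[lo] <- kernel$k0
  if (any(!lo)) {
    rr <- pmin(r[!lo], kernel$r_grid[length(kernel$r_grid)])
    out[!lo] <- exp(stats::approx(log(kernel$r_grid), log(kernel$values),
                                  xout = log(rr), rule = 2)$y)
  }
  out
}

#' @export
print.bgs_kernel <- function(x, ...) {
  cat(sprintf(
    "BGS kernel: %s DDFE (h = %g, scale %s), truncated at s_T = %g\n  %d grid points on [%g, %g]; K(0) = %.4g\n",
    x$family, x$h, format(x$chromosome_scale, digits = 3), x$s_T,
    length(x$r_grid), x$r_grid[1], x$r_grid[length(x$r_grid)], x$k0))
  invisible(x)
}
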