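#' Fit the B baseline to observed silent diversity
#'
#' Ordinary least-squares regression of window `pi_sil` on the predicted
#' background-selection factor `B`, fitted separately per chromosome group
#' (autosomes and X) so that no assumption about the true X/A ratio enters
#' the baseline. Under pure BGS with baseline diversity `theta0`, the
#' expected slope is `theta0` and the intercept 0; the intercept is
#' retained so the fit absorbs deviations from proportionality.
#'
#' @param windows data.frame with columns `pi_sil`, `B` and optionally
#'   `group` (`"autosome"`/`"X"`; default all autosome). Rows with missing
#'   values are dropped.
#' @return object of class `"bgs_baseline"`: per-group `lm` fits.
#' @export
fit_baseline <- function(windows) {
  if (is.null(windows$group)) windows$group <- "autosome"
  windows <- windows[is.finite(windows$pi_sil) & is.finite(windows$B), ]
  fits <- lapply(split(windows, windows$group), function(d) {
    if (nrow(d) < 10)
      stop("need at least 10 windows per group to fit the baseline")
    if (stats::sd(d$B) == 0)
      stop("B is constant within a group; baseline fit is degenerate")
    stats::lm(pi_sil ~ B, data = d)
  })
  structure(list(fits = fits, data = windows), class = "bgs_baseline")
}

#' @export
print.bgs_baseline <- function(x, ...) {
  cat("B-baseline regression of pi_sil on B\n")
  for (g in names(x$fits)) {
    cf <- stats::coef(x$fits[[g]])
    cat(sprintf("  %-9s n = %4d  intercept = %.3g  slope = %.3g  resid sd = %.3g\n",
                g, stats::nobs(x$fits[[g]]), cf[1], cf[2],
                summary(x$fits[[g]])$sigma))
  }
  invisible(x)
}

#' @export
summary.bgs_baseline <- function(object, ...) lapply(object$fits, summary)

#' @export
coef.bgs_baseline <- function(object, ...) t(sapply(object$fits, stats::coef))

#' @export
residuals.bgs_baseline <- function(object, ...)
  unlist(lapply(object$fits, stats::residuals), use.names = FALSE)

#' @export
predict.bgs_baseline <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.null(newdata$group)) newdata$group <- "autosome"
  out <- numeric(nrow(newdata))
  for (g in unique(newdata$group)) {
    i <- newdata$group == g
    out[i] <- stats::predict(object$fits[[g]], newdata = newdata[i, ,
                                                                 drop = FALSE])
  }
  out
}

#' Studentized residuals of the diversity baseline with outlier flags
#'
#' Externally studentized residuals (the observation under test is removed
#' from the error-variance estimate) of the per-group baseline fits, with
#' two-sided P from the t distribution on `n - 3` degrees of freedom,
#' Benjamini-Hochberg q-values, and outlier flags: `deficit` for windows
#' significantly below the baseline (sweep-like), `excess` above
#' (balancing-like), at the nominal level.
#'
#' @param fit a [fit_baseline()] object.
#' @param nominal_p nominal two-sided significance level for flags (0.05).
#' @param fdr_q BH false-discovery-rate level for `q_pass` (0.10).
#' @return data.frame of class `"outlier_table"`: the fitted windows with
#'   `fitted`, `residual`, `pi_sil_R` (studentized residual), `p_value`,
#'   `q_value`, `flag`, `q_pass`.
#' @export
studentized_residuals <- function(fit, nominal_p = 0.05, fdr_q = 0.10) {
  stopifnot(inherits(fit, "bgs_baseline"))
  parts <- lapply(names(fit$fits), function(g) {
    m <- fit$fits[[g]]
    d <- fit$data[fit$data$group == g, , drop = FALSE]
    n <- stats::nobs(m)
    if (n < 5) stop("too few windows for studentized residuals")
    t_i <- suppressWarnings(stats::rstudent(m))
    ## an (essentially) perfect fit has no outliers, only rounding noise
    if (suppressWarnings(summary(m)$sigma) < 1e-10 * stats::sd(m$model[[1]]))
      t_i[] <- 0
    t_i[!is.finite(t_i)] <- 0
    d$fitted <- stats::fitted(m)
    d$residual <- stats::residuals(m)
    d$pi_sil_R <- t_i
    d$p_value <- 2 * stats::pt(-abs(t_i), df = n - 3)
    d
  })
  out <- do.call(rbind, parts)
  bh <- fdr_bh(out$p_value, q_level = fdr_q)
  out$q_value <- bh$q
  out$q_pass <- bh$pass
  out$flag <- ifelse(out$p_value < nominal_p,
                     ifelse(out$residual < 0, "deficit", "excess"), "none")
  rownames(out) <- NULL
  class(out) <- c("outlier_table", "data.frame")
  out
}

#' Chi-square goodness-of-fit of residuals against the standard normal
#'
#' Bins studentized residuals into `n_bins` equal-probability bins of the
#' standard normal and tests observed against expected counts;
#' `df = n_bins - 1`.
#'
#' @param residuals numeric vector of studentized residuals.
#' @param n_bins number of equal-probability bins (default 24).
#' @return list with `chi2`, `df`, `p_value`.
#' @export
normality_check <- function(residuals, n_bins = 24) {
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 5 * n_bins)
    stop("need at least ", 5 * n_bins, " observations for ", n_bins, " bins")
  breaks <- stats::qnorm(seq(0, 1, length.out = n_bins + 1))
  obs <- as.vector(table(cut(residuals, breaks)))
  expected <- n / n_bins
  chi2 <- sum((obs - expected)^2 / expected)
  df <- n_bins - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up BH q-values with pass flags at the given level.
#'
#' @param p vector of P values in `[0, 1]`.
#' @param q_level FDR level (default 0.10).
#' @return list with `q` (adjusted values) and `pass` (logical).
#' @export
fdr_bh <- function(p, q_level = 0.10) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("P values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, pass = !is.na(q) & q < q_level)
}

#' Concordance between diversity residuals and the site-frequency spectrum
#'
#' Spearman correlation between the studentized diversity residuals
#' (`pi_sil_R`) and normalized Tajima's D across matched windows, plus
#' Mann-Whitney comparisons of D between flagged deficit/excess windows
#' and unflagged windows. Under sweeps, diversity deficits should carry
#' singleton-skewed spectra (negative D); balancing-selection excesses the
#' reverse, so a positive correlation is expected.
#'
#' @param outliers an [studentized_residuals()] table.
#' @param tajima vector of normalized Tajima's D aligned with `outliers`
#'   rows (or a `window_diversity` table with matching `start`).
#' @return list with `rho`, `p_value`, and per-flag Mann-Whitney results.
#' @export
concordance <- function(outliers, tajima) {
  if (is.data.frame(tajima))
    tajima <- tajima$tajima_d_norm[match(outliers$start, tajima$start)]
  ok <- is.finite(outliers$pi_sil_R) & is.finite(tajima)
  if (sum(ok) < 5) stop("fewer than 5 matched windows")
  ct <- suppressWarnings(
    stats::cor.test(outliers$pi_sil_R[ok], tajima[ok],
                    method = "spearman", exact = FALSE))
  mwu <- function(flag) {
    a <- tajima[ok & outliers$flag == flag]
    b <- tajima[ok & outliers$flag == "none"]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    w <- suppressWarnings(stats::wilcox.test(a, b))
    list(n = length(a), W = unname(w$statistic), p_value = w$p.value)
  }
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = sum(ok), deficit_vs_none = mwu("deficit"),
       excess_vs_none = mwu("excess"))
}
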