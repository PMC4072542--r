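#' Build the per-class exponent kernels of a BGS model
#'
#' Single-DDFE models share one kernel between coding and noncoding site
#' classes; the two-DDFE hybrids get one per class. Precompute once and
#' pass to [compute_B()] when mapping several chromosomes or variants of
#' a model.
#'
#' @param model a [parse_model_id()] configuration.
#' @param n_grid kernel grid resolution (default 512).
#' @return list with elements `coding` and `noncoding` ([build_kernel()]
#'   objects).
#' @export
model_kernels <- function(model, n_grid = 512) {
  kc <- build_kernel(model$ddfe_coding, model$threshold, n_grid = n_grid)
  kn <- if (model$hybrid)
    build_kernel(model$ddfe_noncoding, model$threshold, n_grid = n_grid)
  else kc
  list(coding = kc, noncoding = kn)
}

## Effective per-site deleterious rates per class under a model.
model_rates <- function(model, u_te = 0) {
  list(coding = effective_deleterious_rate(model$u + u_te,
                                           model$ddfe_coding, model$threshold),
       noncoding = effective_deleterious_rate(model$u + u_te,
                                              model$ddfe_noncoding,
                                              model$threshold))
}

#' Compute the B landscape of a chromosome at 1-kb resolution
#'
#' For each 1-kb window `j`, the BGS exponent sums contributions from every
#' window `i` of the chromosome:
#' `E_j = sum_i (Naa_i u_aa K_cod(r_ji) + (Nutr_ss_i + Nnc_ss_i) u_nc K_nc(r_ji))`
#' and `B_j = exp(-E_j)`, with `r_ji` the recombination frequency between
#' window centers (same-window pairs fully linked) and `K` the truncated-
#' DDFE kernel. Per-class effective rates are the model's per-bp rate
#' scaled by the fraction of mutations above the neutral threshold.
#'
#' @param track a [count_selected_sites()] result.
#' @param map a [recmap()] object covering the same chromosome. Its
#'   `sex_factor` must match the model's chromosome type.
#' @param model a [parse_model_id()] configuration.
#' @param kernels optional precomputed [model_kernels()] (reused across
#'   chromosomes for speed).
#' @param u_te additional per-bp TE deleterious insertion rate applied
#'   uniformly over selected sites (default 0; the standard-mutation models
#'   already fold TE load into `u`).
#' @return data.frame of class `"b_landscape"`: per-window `B` and exponent
#'   `E`, with the model id as attribute.
#' @export
compute_B <- function(track, map, model = parse_model_id(),
                      kernels = NULL, u_te = 0) {
  stopifnot(inherits(track, "selected_track"), inherits(map, "recmap"))
  if (track$chromosome[1] != map$chromosome)
    stop("track and map describe different chromosomes")
  if (max(track$end) > max(map$end) + 1e-6)
    stop("selected-site track extends beyond the recombination map")
  if (is.null(kernels)) kernels <- model_kernels(model)
  rates <- model_rates(model, u_te)

  centers <- (track$start + track$end) / 2
  g <- recmap_genetic_pos(map, centers)
  load_cod <- track$Naa * rates$coding
  load_nc <- (track$Nutr_ss + track$Nnc_ss) * rates$noncoding
  W <- length(centers)
  E <- numeric(W)
  shared <- identical(kernels$coding, kernels$noncoding)
  chunk <- 256L
  for (a in seq(1L, W, by = chunk)) {
    b <- min(a + chunk - 1L, W)
    Dg <- abs(outer(g[a:b], g, "-"))
    r <- Dg
    if (model$include_gc)
      r <- r + gc_term(abs(outer(centers[a:b], centers, "-")),
                       model$gamma_gc, model$L_gc)
    r <- map$sex_factor * r
    r[cbind(seq_len(b - a + 1L), a:b)] <- 0   # same-window: fully linked
    r[r < 1e-10] <- 0
    r[r > 1] <- 1
    if (shared) {
      K <- matrix(kernel_eval(kernels$coding, r), nrow = b - a + 1L)
      E[a:b] <- as.vector(K %*% (load_cod + load_nc))
    } else {
      Kc <- matrix(kernel_eval(kernels$coding, r), nrow = b - a + 1L)
      Kn <- matrix(kernel_eval(kernels$noncoding, r), nrow = b - a + 1L)
      E[a:b] <- as.vector(Kc %*% load_cod + Kn %*% load_nc)
    }
  }
  out <- data.frame(chromosome = track$chromosome, start = track$start,
                    end = track$end, B = exp(-E), E = E)
  attr(out, "model_id") <- model$model_id
  class(out) <- c("b_landscape", "data.frame")
  out
}

#' @export
print.b_landscape <- function(x, ...) {
  cat(sprintf("B landscape [%s] %s: %d windows of %g kb\n",
              attr(x, "model_id"), x$chromosome[1], nrow(x),
              (x$end[1] - x$start[1]) / 1000))
  cat(sprintf("  median B = %.3f, range [%.3f, %.3f], %.1f%% of windows with B < 0.25\n",
              stats::median(x$B), min(x$B), max(x$B),
              100 * mean(x$B < 0.25)))
  invisible(x)
}

#' @export
summary.b_landscape <- function(object, ...) {
  s <- c(stats::quantile(object$B, c(0.05, 0.25, 0.5, 0.75, 0.95)),
         frac_below_0.25 = mean(object$B < 0.25))
  structure(list(model_id = attr(object, "model_id"),
                 chromosome = object$chromosome[1],
                 n_windows = nrow(object), stats = s),
            class = "summary.b_landscape")
}

#' @export
print.summary.b_landscape <- function(x, ...) {
  cat(sprintf("B landscape [%s] %s (%d windows)\n", x$model_id,
              x$chromosome, x$n_windows))
  print(round(x$stats, 4))
  invisible(x)
}

#' @export
plot.b_landscape <- function(x, ...) {
  graphics::plot((x$start + x$end) / 2e6, x$B, type = "l",
                 xlab = "position (Mb)", ylab = "B", ylim = c(0, 1),
                 main = attr(x, "model_id"), ...)
  invisible(x)
}

#' Brute-force per-bp B (validation oracle)
#'
#' Computes `B` at given focal positions by a direct double loop over
#' focal position x selected base pair, with per-pair recombination from
#' the map and the DDFE integral evaluated by dense trapezoid quadrature
#' on the log-`s` scale -- no precomputed kernel grid and no aggregation
#' of selected sites into windows. Intended to validate [compute_B()] on
#' small fixtures; refuses chromosomes over 200 kb.
#'
#' @param classes a [classify_sites()] result (per-bp labels).
#' @param map a [recmap()] object.
#' @param model a [parse_model_id()] configuration.
#' @param focal_pos focal positions in bp (default: 1-kb window centers).
#' @param config a [site_class_config()].
#' @param n_nodes quadrature nodes on the log-`s` scale (default 300).
#' @param u_te additional TE insertion rate, as in [compute_B()].
#' @return data.frame with `pos`, `B`, `E`.
#' @export
oracle_B <- function(classes, map, model = parse_model_id(),
                     focal_pos = NULL, config = site_class_config(),
                     n_nodes = 300, u_te = 0) {
  stopifnot(inherits(classes, "site_classes"))
  L <- classes$length
  if (L > 200000) stop("oracle_B refuses chromosomes over 200 kb")
  if (is.null(focal_pos))
    focal_pos <- seq(500, L - 500, by = 1000)
  rates <- model_rates(model, u_te)
  lab <- classes$labels
  w_cod <- (lab == 1L) * config$coding_nonsyn_fraction * config$cs_nonsyn *
    rates$coding
  w_nc <- ((lab == 2L) * config$cs_utr + (lab == 3L) * config$cs_intron +
           (lab == 4L) * config$cs_intergenic) * rates$noncoding
  bp_pos <- seq_len(L) - 0.5          # base midpoints, 0-based coordinates

  ## trapezoid nodes/weights of the truncated, renormalized, clamped DDFE
  nodes <- function(spec) {
    s_T <- model$threshold$s_T
    if (spec$family == "point_mass") {
      s0 <- min(spec$params$mean_s * spec$chromosome_scale, 1)
      return(list(s = s0, w = 1))
    }
    x <- seq(log(s_T), 0, length.out = n_nodes)
    dx <- x[2] - x[1]
    wt <- ddfe_log_density(spec, x) * dx
    wt[c(1, n_nodes)] <- wt[c(1, n_nodes)] / 2
    mass <- 1 - ddfe_cdf(spec, s_T)
    list(s = c(exp(x), 1),
         w = c(wt, 1 - ddfe_cdf(spec, 1)) / mass)
  }
  qsets <- if (model$hybrid)
    list(list(nd = nodes(model$ddfe_coding), w = w_cod),
         list(nd = nodes(model$ddfe_noncoding), w = w_nc))
  else
    list(list(nd = nodes(model$ddfe_coding), w = w_cod + w_nc))

  h <- model$ddfe_coding$dominance_h
  E <- numeric(length(focal_pos))
  for (f in seq_along(focal_pos)) {
    r <- pairwise_r(map, focal_pos[f], bp_pos,
                    include_gc = model$include_gc)
    for (qs in qsets) {
      sel <- qs$w > 0
      rs <- r[sel]; ws <- qs$w[sel]
      acc <- 0
      for (m in seq_along(qs$nd$s))
        acc <- acc + qs$nd$w[m] * sum(ws * bgs_g(qs$nd$s[m], h, rs))
      E[f] <- E[f] + acc
    }
  }
  data.frame(pos = focal_pos, B = exp(-E), E = E)
}

#' Genomic scale of the BGS effect at a focal window (D_B quantiles)
#'
#' Around a focal 1-kb window, grows a symmetric physical interval (1 kb
#' per step per side) until the interval's summed BGS exponent reaches the
#' requested fraction of the full-chromosome exponent, and reports the
#' interval size in physical (kb) and genetic (cM per female meiosis)
#' units.
#'
#' @inheritParams compute_B
#' @param focal_window 1-based index of the focal window.
#' @param fractions fractions of the total exponent (default 0.5/0.75/0.9).
#' @return data.frame with one row per fraction: `fraction`, `physical_kb`,
#'   `genetic_cM`; `NA` rows if the focal exponent is 0.
#' @export
db_quantiles <- function(track, map, model = parse_model_id(),
                         focal_window, fractions = c(0.5, 0.75, 0.9),
                         kernels = NULL, u_te = 0) {
  stopifnot(inherits(track, "selected_track"))
  if (is.null(kernels)) kernels <- model_kernels(model)
  rates <- model_rates(model, u_te)
  centers <- (track$start + track$end) / 2
  g <- recmap_genetic_pos(map, centers)
  j <- as.integer(focal_window)
  W <- length(centers)
  if (j < 1L || j > W) stop("focal_window out of range")
  r <- abs(g - g[j])
  if (model$include_gc)
    r <- r + gc_term(abs(centers - centers[j]), model$gamma_gc, model$L_gc)
  r <- map$sex_factor * r
  r[j] <- 0
  r[r < 1e-10] <- 0
  r[r > 1] <- 1
  contrib <- kernel_eval(kernels$coding, r) * track$Naa * rates$coding +
    kernel_eval(kernels$noncoding, r) *
      (track$Nutr_ss + track$Nnc_ss) * rates$noncoding
  E_tot <- sum(contrib)
  if (E_tot <= 0)
    return(data.frame(fraction = fractions, physical_kb = NA_real_,
                      genetic_cM = NA_real_))
  window_kb <- (track$end[1] - track$start[1]) / 1000
  res <- lapply(sort(fractions), function(f) {
    target <- f * E_tot
    for (hw in 0:(W - 1L)) {
      lo <- max(1L, j - hw); hi <- min(W, j + hw)
      if (sum(contrib[lo:hi]) >= target - 1e-12 * E_tot) {
        return(data.frame(
          fraction = f,
          physical_kb = (hi - lo + 1L) * window_kb,
          genetic_cM = (recmap_genetic_pos(map, track$end[hi]) -
                        recmap_genetic_pos(map, track$start[lo])) * 100))
      }
    }
    data.frame(fraction = f, physical_kb = W * window_kb,
               genetic_cM = (recmap_genetic_pos(map, track$end[W]) -
                             recmap_genetic_pos(map, track$start[1])) * 100)
  })
  do.call(rbind, res)
}

#' X-to-autosome summary of predicted diversity
#'
#' Median `B` per chromosome group and the predicted X/A diversity ratio
#' `0.75 * median(B_X) / median(B_A)` (equal sex numbers assumed).
#'
#' @param autosomal a `b_landscape` or list of them.
#' @param x_landscape the X-chromosome `b_landscape`.
#' @return list with `median_B_autosome`, `median_B_X`, `xa_ratio`.
#' @export
xa_summary <- function(autosomal, x_landscape) {
  if (inherits(autosomal, "b_landscape")) autosomal <- list(autosomal)
  ba <- unlist(lapply(autosomal, function(l) l$B))
  bx <- x_landscape$B
  if (!length(ba) || !length(bx)) stop("empty landscape")
  mA <- stats::median(ba); mX <- stats::median(bx)
  list(median_B_autosome = mA, median_B_X = mX,
       xa_ratio = 0.75 * mX / mA)
}

#' Aggregate a 1-kb B landscape to coarser windows
#'
#' @param landscape a `b_landscape`.
#' @param window_bp target window size (multiple of the native size).
#' @return a `b_landscape` at the coarser resolution (mean B per window).
#' @export
aggregate_b <- function(landscape, window_bp) {
  native <- landscape$end[1] - landscape$start[1]
  if (window_bp %% native != 0)
    stop("window_bp must be a multiple of the native window size")
  grp <- landscape$start %/% window_bp
  cnt <- as.vector(rowsum(rep(1, nrow(landscape)), grp, reorder = TRUE))
  B <- as.vector(rowsum(landscape$B, grp, reorder = TRUE)) / cnt
  E <- as.vector(rowsum(landscape$E, grp, reorder = TRUE)) / cnt
  start <- sort(unique(grp)) * window_bp
  out <- data.frame(chromosome = landscape$chromosome[1], start = start,
                    end = start + window_bp, B = B, E = E)
  attr(out, "model_id") <- attr(landscape, "model_id")
  class(out) <- c("b_landscape", "data.frame")
  out
}

#' Write a B landscape as BedGraph-compatible TSV
#'
#' @param landscape a `b_landscape`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_b_track <- function(landscape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model_id=%s bgsmap=%s", attr(landscape, "model_id"),
                     as.character(utils::packageVersion("bgsmap"))), con)
  utils::write.table(
    data.frame(landscape$chromosome, as.integer(landscape$start),
               as.integer(landscape$end), signif(landscape$B, 10)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
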