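test_that("point-mass kernel has the closed form", {
  pm <- ddfe("point_mass", mean_s = 0.01)
  k <- build_kernel(pm, neutral_threshold(1e6))
  sh <- 0.01 * 0.5
  expect_equal(k$k0, 1 / sh)
  expect_equal(kernel_eval(k, 0), 1 / sh)
  for (r in c(1e-6, 1e-4, 1e-2, 0.5)) {
    expect_equal(kernel_eval(k, r), sh / (sh + r * (1 - sh))^2,
                 tolerance = 1e-4)   # grid interpolation error only
  }
})

test_that("lognormal kernel matches an independent fine-grid trapezoid", {
  ln <- ddfe("lognormal", median_s = 2.31e-4, sd_log = 5.308)
  thr <- neutral_threshold(1e6)
  k <- build_kernel(ln, thr)
  ## independent oracle: dense trapezoid over ln s of the truncated,
  ## renormalized density (lethal mass clamped at s = 1)
  trap <- function(r, n = 20001) {
    x <- seq(log(thr$s_T), 0, length.out = n)
    s <- exp(x)
    f <- dnorm(x, log(2.31e-4), 5.308) * (0.5 * s) /
      (0.5 * s + r * (1 - 0.5 * s))^2
    w <- rep(x[2] - x[1], n); w[c(1, n)] <- w[1] / 2
    lethal <- plnorm(1, log(2.31e-4), 5.308, lower.tail = FALSE)
    (sum(f * w) + lethal * 0.5 / (0.5 + r * 0.5)^2) /
      (1 - plnorm(thr$s_T, log(2.31e-4), 5.308))
  }
  for (r in c(1e-10, 1e-7, 1e-5, 1e-3, 1e-1, 1)) {
    i <- which.min(abs(k$r_grid - r))
    expect_equal(k$values[i], trap(k$r_grid[i]), tolerance = 1e-4)
  }
  expect_true(all(diff(k$values) <= 0))   # nonincreasing in r
  expect_true(all(k$values > 0))
})

test_that("B is 1 with no selected sites and has closed form at r = 0", {
  fx <- fixture_small()
  ## zero-selection track
  tr0 <- fx$track
  tr0$Naa <- tr0$Nutr_ss <- tr0$Nnc_ss <- 0
  bl0 <- compute_B(tr0, fx$map, parse_model_id())
  expect_equal(bl0$B, rep(1, nrow(bl0)))

  ## fully linked chromosome (c = 0, no GC), point-mass DDFE:
  ## B = exp(-sum(u_i) / (s h)) at every focal window
  m <- point_mass_model(s = 0.01, include_gc = FALSE)
  map0 <- flat_map(0, 1e5)
  bl <- compute_B(fx$track, map0, m)
  u_eff <- m$u   # point mass above s_T: no neutral mass removed
  total_load <- sum(fx$track$Naa + fx$track$Nutr_ss + fx$track$Nnc_ss) * u_eff
  expect_equal(bl$B, rep(exp(-total_load / (0.01 * 0.5)), nrow(bl)),
               tolerance = 1e-10)
})

test_that("the fully-linked limit reproduces exp(-U/(2 s h))", {
  ## classical zero-recombination result with per-haploid-copy u:
  ## sum over sites of u equals U_diploid / 2
  m <- point_mass_model(s = 0.02)
  map0 <- flat_map(0, 1e4)
  labels <- rep(4L, 1e4)   # all intergenic
  cls <- structure(list(chromosome = "chrS", length = 1e4, labels = labels,
                        levels = c("coding", "utr", "intron",
                                   "intergenic", "masked")),
                   class = "site_classes")
  ## count every base as selected to make U explicit
  tr <- count_selected_sites(cls, site_class_config(1, 1, 1, 1, 1))
  bl <- compute_B(tr, map0, m, kernels = NULL)
  U_diploid <- 2 * 1e4 * m$u
  expect_equal(bl$B[1], exp(-U_diploid / (2 * 0.02 * 0.5)),
               tolerance = 1e-10)
})

test_that("exponent is exactly linear in the mutation rate", {
  fx <- fixture_small()
  m1 <- parse_model_id("M_LN,StdMut,CO+GC")
  m2 <- m1; m2$u <- 2 * m1$u
  k <- model_kernels(m1)
  b1 <- compute_B(fx$track, fx$map, m1, kernels = k)
  b2 <- compute_B(fx$track, fx$map, m2, kernels = k)
  expect_equal(b2$E, 2 * b1$E, tolerance = 1e-12)
  expect_equal(b2$B, b1$B^2, tolerance = 1e-10)
})

test_that("B is monotone in recombination and in selection density", {
  fx <- fixture_small()
  m <- parse_model_id()
  k <- model_kernels(m)
  b_lo <- compute_B(fx$track, flat_map(0.5, 1e5), m, kernels = k)
  b_hi <- compute_B(fx$track, flat_map(5, 1e5), m, kernels = k)
  expect_true(all(b_hi$B >= b_lo$B - 1e-12))

  more <- fx$track
  more$Nnc_ss <- more$Nnc_ss + 100
  b_more <- compute_B(more, fx$map, m, kernels = k)
  b_base <- compute_B(fx$track, fx$map, m, kernels = k)
  expect_true(all(b_more$B <= b_base$B + 1e-12))
})

test_that("disjoint selected-site sets act multiplicatively on B", {
  fx <- fixture_small()
  m <- parse_model_id()
  k <- model_kernels(m)
  half1 <- half2 <- fx$track
  idx <- seq_len(nrow(fx$track)) <= 50
  for (col in c("Naa", "Nutr_ss", "Nnc_ss")) {
    half1[[col]][!idx] <- 0
    half2[[col]][idx] <- 0
  }
  b1 <- compute_B(half1, fx$map, m, kernels = k)
  b2 <- compute_B(half2, fx$map, m, kernels = k)
  ball <- compute_B(fx$track, fx$map, m, kernels = k)
  expect_equal(ball$B, b1$B * b2$B, tolerance = 1e-10)
})

test_that("gene conversion weakens predicted linkage effects", {
  fx <- fixture_small()
  b_gc <- compute_B(fx$track, fx$map, parse_model_id("M_LN,StdMut,CO+GC"))
  b_co <- compute_B(fx$track, fx$map, parse_model_id("M_LN,StdMut,CO"))
  expect_true(all(b_gc$B >= b_co$B - 1e-12))
  expect_gt(median(b_gc$B), median(b_co$B))
})

test_that("D_B quantiles behave on constructed landscapes", {
  m <- point_mass_model(s = 0.01)
  map <- flat_map(2, 1e5)
  mk_track <- function(nnc) {
    n <- length(nnc)
    structure(data.frame(
      chromosome = "chrS", start = (seq_len(n) - 1) * 1000,
      end = seq_len(n) * 1000, coding_bp = 0, utr_bp = 0, intron_bp = 0,
      intergenic_bp = 0, masked_bp = 0, Naa = 0, Nutr_ss = 0,
      Nnc_ss = nnc, n_silent_candidate = 0),
      class = c("selected_track", "data.frame"))
  }
  ## all selection in one cluster right of the focal window
  nnc <- rep(0, 100); nnc[52:54] <- 500
  db <- db_quantiles(mk_track(nnc), map, m, focal_window = 50,
                     fractions = c(0.9, 1.0))
  expect_lte(db$physical_kb[1], 9)      # interval reaches the cluster only
  expect_equal(db$physical_kb[2], 9)    # fraction 1: symmetric span to it
  expect_true(all(diff(db$physical_kb) >= 0))

  ## uniform selection, uniform c: compare against a direct cumulative scan
  nncu <- rep(100, 100)
  tru <- mk_track(nncu)
  dbu <- db_quantiles(tru, map, m, focal_window = 50)
  k <- build_kernel(m$ddfe_coding, m$threshold)
  centers <- (tru$start + tru$end) / 2
  r <- pairwise_r(map, rep(centers[50], 100), centers)
  contrib <- kernel_eval(k, r) * nncu * m$u
  cum <- function(hw) sum(contrib[max(1, 50 - hw):min(100, 50 + hw)])
  expected_kb <- function(f) {
    hw <- which(vapply(0:99, cum, numeric(1)) >=
                  f * sum(contrib) - 1e-12 * sum(contrib))[1] - 1
    (min(100, 50 + hw) - max(1, 50 - hw) + 1)
  }
  expect_equal(dbu$physical_kb, vapply(c(0.5, 0.75, 0.9), expected_kb,
                                       numeric(1)))
  expect_true(all(diff(dbu$physical_kb) >= 0))
  expect_true(all(diff(dbu$genetic_cM) >= 0))
  ## fraction 1 covers the whole chromosome
  db1 <- db_quantiles(tru, map, m, focal_window = 50, fractions = 1)
  expect_equal(db1$physical_kb, 100)
})

test_that("X/A summary reports 0.75 * median ratio", {
  mk_bl <- function(B) structure(
    data.frame(chromosome = "c", start = seq_along(B) * 1000 - 1000,
               end = seq_along(B) * 1000, B = B, E = -log(B)),
    class = c("b_landscape", "data.frame"))
  same <- xa_summary(mk_bl(rep(0.6, 20)), mk_bl(rep(0.6, 20)))
  expect_equal(same$xa_ratio, 0.75)
  s2 <- xa_summary(mk_bl(rep(0.75, 20)), mk_bl(rep(1, 20)))
  expect_equal(s2$xa_ratio, 1.0)
  expect_error(xa_summary(list(), mk_bl(rep(1, 5))), "empty")
})
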