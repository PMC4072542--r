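test_that("per-site pi handles coverage, identity and small samples", {
  expect_equal(per_site_pi(rep("A", 10)), 0)
  expect_true(is.na(per_site_pi(c(rep("A", 5), rep("N", 6)))))   # 5 non-N
  expect_true(is.na(per_site_pi(character(0))))
  ## 2 sequences, 1 difference: per-site pi = 1 (n/(n-1) * 1/2 * 2)
  expect_equal(per_site_pi(c("A", "G"), min_coverage = 2), 1)
  ## frequency formula with the unbiased correction
  a <- c(rep("A", 7), rep("G", 3))
  expect_equal(per_site_pi(a), (10 / 9) * (1 - 0.7^2 - 0.3^2))
})

test_that("window diversity matches the all-pairs oracle and is order-invariant", {
  set.seed(21)
  n <- 6; L <- 2000
  aln <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                       prob = c(0.85, 0.05, 0.05, 0.05)), nrow = n)
  aln[sample(length(aln), 200)] <- "N"
  cls <- structure(list(chromosome = "chrT", length = L,
                        labels = rep(4L, L),
                        levels = c("coding", "utr", "intron", "intergenic",
                                   "masked")),
                   class = "site_classes")
  wd <- window_diversity(aln, cls, window_bp = 1000, min_coverage = 4,
                         min_silent = 0)
  ## all-pairs oracle: the fraction of differing pairs per site equals
  ## the sample-size-corrected diversity
  pair_pi <- function(cols) {
    out <- numeric(length(cols))
    for (i in seq_along(cols)) {
      a <- aln[, cols[i]]; a <- a[a != "N"]; m <- length(a)
      if (m < 4) { out[i] <- NA_real_; next }
      diffs <- 0; pairs <- 0
      for (p in 1:(m - 1)) for (q in (p + 1):m) {
        diffs <- diffs + (a[p] != a[q]); pairs <- pairs + 1
      }
      out[i] <- diffs / pairs * 1  # mean pairwise difference per site
    }
    out
  }
  v1 <- pair_pi(1:1000)
  expect_equal(wd$pi_sil[1], mean(v1, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(wd$n_silent_sites[1], sum(!is.na(v1)))
  ## permuting sequences changes nothing
  wd2 <- window_diversity(aln[sample(n), ], cls, window_bp = 1000,
                          min_coverage = 4, min_silent = 0)
  expect_equal(wd2$pi_sil, wd$pi_sil)
})

test_that("windows with too few silent sites are excluded", {
  L <- 1000
  labels <- c(rep(1L, 600), rep(4L, 400))   # only 400 silent bases
  cls <- structure(list(chromosome = "chrT", length = L, labels = labels,
                        levels = c("coding", "utr", "intron", "intergenic",
                                   "masked")),
                   class = "site_classes")
  sites <- data.frame(pos = 700L, n = 12L, derived = 3L)
  wd <- window_diversity(sites, cls, n_total = 12)
  expect_false(wd$included[1])
  ## monomorphic but well-covered window is included
  cls$labels <- rep(4L, L)
  wd2 <- window_diversity(data.frame(pos = integer(0), n = integer(0),
                                     derived = integer(0)),
                          cls, n_total = 12)
  expect_true(wd2$included[1])
  expect_equal(wd2$pi_sil[1], 0)
})

test_that("normalized Tajima's D matches a textbook computation", {
  ## worked example: n = 10, folded SFS counts [3, 2, 1]
  n <- 10; sfs <- c(3, 2, 1)
  S <- 6
  a1 <- sum(1 / 1:9); a2 <- sum(1 / (1:9)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pi_tot <- sum(sfs * (1:3) * (n - 1:3) * 2 / (n * (n - 1)))
  D <- (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  pi_min <- S * 2 / n
  Dmin <- (pi_min - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajima_d_normalized(n, sfs), D / abs(Dmin), tolerance = 1e-12)

  ## all singletons reach the lower bound exactly
  expect_equal(tajima_d_normalized(12, c(7)), -1)
  expect_equal(tajima_d_normalized(12, c(1)), -1)
  ## no segregating sites: undefined
  expect_true(is.na(tajima_d_normalized(12, integer(0))))
  expect_error(tajima_d_normalized(3, c(1)), "at least 4")
  ## intermediate-frequency variants give positive values
  expect_gt(tajima_d_normalized(10, c(0, 0, 0, 0, 4)), 0)
})

test_that("equilibrium-neutral synthetic data has near-zero mean D/Dmin", {
  fx <- fixture_1mb()
  bl <- fixture_b_1mb()
  poly <- generate_polymorphism(bl, fx$classes, fx$spec, seed = 99)
  wd <- window_diversity(poly$sites, fx$classes, window_bp = 10000,
                         n_total = poly$n_haplotypes)
  d <- wd$tajima_d_norm[wd$included & is.finite(wd$tajima_d_norm)]
  expect_gt(length(d), 50)
  expect_lt(abs(mean(d)), 0.1)
})
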