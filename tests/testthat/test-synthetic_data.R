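test_that("generators are byte-identical given the seed", {
  spec <- synthetic_spec(seed = 13, chromosome_length = 5e4, n_genes = 5,
                         crossover_profile = "constant")
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- generate_genome(spec, d1)
  g2 <- generate_genome(spec, d2)
  for (f in c("gff3", "te_bed", "recmap_tsv"))
    expect_identical(readLines(g1[[f]]), readLines(g2[[f]]))
  cls <- classify_sites(g1$gff3, te_bed = g1$te_bed, chrom_length = 5e4)
  bl <- compute_B(count_selected_sites(cls), g1$recmap, parse_model_id())
  p1 <- generate_polymorphism(bl, cls, spec)
  p2 <- generate_polymorphism(bl, cls, spec)
  expect_identical(p1$sites, p2$sites)
  t1 <- generate_gene_table(bl, spec)
  expect_identical(t1, generate_gene_table(bl, spec))
  ## a different seed changes the draw
  p3 <- generate_polymorphism(bl, cls, spec, seed = 14)
  expect_false(identical(p1$sites, p3$sites))
})

test_that("generated files round-trip through the package readers cleanly", {
  fx <- fixture_small()
  expect_no_warning(classify_sites(fx$gen$gff3, te_bed = fx$gen$te_bed,
                                   chrom_length = fx$spec$chromosome_length))
  expect_no_warning(read_recmap(fx$gen$recmap_tsv))
  m <- read_recmap(fx$gen$recmap_tsv)
  expect_equal(m$c_cM_Mb, fx$map$c_cM_Mb)
})

test_that("degenerate specs behave: no genes, zero diversity, bad features", {
  spec0 <- synthetic_spec(seed = 2, chromosome_length = 2e4, n_genes = 0,
                          crossover_profile = "constant")
  g0 <- generate_genome(spec0, tempfile())
  cls0 <- classify_sites(g0$gff3, chrom_length = 2e4)
  expect_true(all(cls0$labels == 4L))   # all intergenic

  ## theta0 = 0: monomorphic sample
  specz <- synthetic_spec(seed = 2, chromosome_length = 2e4, n_genes = 2,
                          theta0 = 0, crossover_profile = "constant")
  gz <- generate_genome(specz, tempfile())
  clz <- classify_sites(gz$gff3, te_bed = gz$te_bed, chrom_length = 2e4)
  blz <- compute_B(count_selected_sites(clz), gz$recmap, parse_model_id())
  pz <- generate_polymorphism(blz, clz, specz)
  expect_equal(nrow(pz$sites), 0L)

  expect_error(synthetic_spec(planted_features = data.frame(
    pos = 9e5, span = 2e5, kind = "sweep", multiplier = 0.2)), "beyond")
  expect_error(synthetic_spec(planted_features = data.frame(
    pos = 1e5, span = 1e4, kind = "duplication", multiplier = 2)), "kind")
  expect_error(synthetic_spec(chromosome_length = 1e4, n_genes = 10),
               "tile")
})

test_that("window diversity of generated polymorphism tracks theta0 * B", {
  fx <- fixture_1mb()
  bl <- fixture_b_1mb()
  poly <- generate_polymorphism(bl, fx$classes, fx$spec, seed = 55)
  wd <- window_diversity(poly$sites, fx$classes,
                         n_total = poly$n_haplotypes)
  d <- join_b(wd[wd$included, ], bl)
  fit <- fit_baseline(d)
  cf <- summary(fit)[["autosome"]]$coefficients
  ## slope ~ theta0, intercept ~ 0
  expect_lt(abs(cf["B", "Estimate"] - fx$spec$theta0),
            3 * cf["B", "Std. Error"])
  expect_lt(abs(cf["(Intercept)", "Estimate"]),
            3 * cf["(Intercept)", "Std. Error"] + 1e-4)
})

test_that("planted features shift diversity and the frequency spectrum", {
  spec <- synthetic_spec(seed = 77, planted_features = data.frame(
    pos = c(3e5, 65e4), span = c(3e4, 3e4),
    kind = c("sweep", "balanced"), multiplier = c(0.2, 3)))
  fx <- fixture_1mb()
  poly <- generate_polymorphism(fixture_b_1mb(), fx$classes, spec)
  wd <- window_diversity(poly$sites, fx$classes, window_bp = 10000,
                         n_total = poly$n_haplotypes)
  bl10 <- aggregate_b(fixture_b_1mb(), 10000)
  d <- join_b(wd, bl10)
  sweep_w <- d$start >= 3e5 & d$end <= 33e4
  bal_w <- d$start >= 65e4 & d$end <= 68e4
  none_w <- !sweep_w & !bal_w & d$included
  expect_lt(mean(d$pi_sil[sweep_w] / d$B[sweep_w]),
            0.5 * mean(d$pi_sil[none_w] / d$B[none_w]))
  expect_gt(mean(d$pi_sil[bal_w] / d$B[bal_w]),
            2 * mean(d$pi_sil[none_w] / d$B[none_w]))
  ## SFS tilt: sweeps singleton-heavy (D << 0), balanced the reverse
  expect_lt(mean(d$tajima_d_norm[sweep_w]), -0.3)
  expect_gt(mean(d$tajima_d_norm[bal_w]), mean(d$tajima_d_norm[none_w]))
})

test_that("planted filter violations are removed exactly by filter_genes", {
  fx <- fixture_1mb()
  d <- generate_gene_table(fixture_b_1mb(), fx$spec, violation_rate = 0.1,
                           seed = 88)
  expect_equal(sum(d$planted_violation), 10)
  f <- filter_genes(d)
  expect_equal(nrow(f$retained), 90)
  expect_false(any(f$retained$planted_violation))
})

test_that("FASTA export of a polymorphism sample matches the site table", {
  spec <- synthetic_spec(seed = 5, chromosome_length = 2e4, n_genes = 2,
                         crossover_profile = "constant")
  gen <- generate_genome(spec, tempfile())
  cls <- classify_sites(gen$gff3, te_bed = gen$te_bed, chrom_length = 2e4)
  bl <- compute_B(count_selected_sites(cls), gen$recmap, parse_model_id())
  poly <- generate_polymorphism(bl, cls, spec)
  fa <- tempfile(fileext = ".fa")
  write_alignment_fasta(poly, 2e4, fa)
  aln <- read_alignment(fa)
  expect_equal(dim(aln), c(15, 2e4))
  ## derived counts in the alignment equal the site table
  seg <- colSums(aln == "G")
  expect_equal(unname(seg[poly$sites$pos]), poly$sites$derived)
  expect_equal(sum(seg > 0), nrow(poly$sites))
  ## alignment-based diversity equals site-table diversity
  wd_a <- window_diversity(aln, cls, n_total = 15)
  wd_s <- window_diversity(poly$sites, cls, n_total = 15)
  expect_equal(wd_a$pi_sil, wd_s$pi_sil, tolerance = 1e-12)
})
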