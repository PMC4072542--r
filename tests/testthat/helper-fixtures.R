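## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## 100-kb, 10-gene chromosome with a flat crossover map: the oracle fixture.
fixture_small <- function() memo("small", {
  spec <- synthetic_spec(seed = 7, chromosome_length = 1e5, n_genes = 10,
                         crossover_profile = "constant")
  gen <- generate_genome(spec, file.path(tempdir(), "bgsmap-small"))
  cls <- classify_sites(gen$gff3, te_bed = gen$te_bed,
                        chrom_length = spec$chromosome_length)
  list(spec = spec, gen = gen, classes = cls,
       track = count_selected_sites(cls), map = gen$recmap)
})

## The standard 1-Mb, 100-gene genome with a hot-cold crossover profile.
fixture_1mb <- function() memo("1mb", {
  spec <- synthetic_spec(seed = 42)
  gen <- generate_genome(spec, file.path(tempdir(), "bgsmap-1mb"))
  cls <- classify_sites(gen$gff3, te_bed = gen$te_bed,
                        chrom_length = spec$chromosome_length)
  list(spec = spec, gen = gen, classes = cls,
       track = count_selected_sites(cls), map = gen$recmap)
})

## Default-model B landscape on the 1-Mb genome.
fixture_b_1mb <- function() memo("b_1mb", {
  fx <- fixture_1mb()
  compute_B(fx$track, fx$map, parse_model_id())
})

## Outlier-power fixture: a 3-Mb chromosome scanned in 10-kb windows, so
## that the handful of planted windows cannot distort the baseline fit
## (the genome scans the method is built for have 1e4-1e5 windows).
fixture_3mb <- function() memo("3mb", {
  spec <- synthetic_spec(seed = 42, chromosome_length = 3e6, n_genes = 300)
  gen <- generate_genome(spec, file.path(tempdir(), "bgsmap-3mb"))
  cls <- classify_sites(gen$gff3, te_bed = gen$te_bed,
                        chrom_length = spec$chromosome_length)
  track <- count_selected_sites(cls)
  b <- compute_B(track, gen$recmap, parse_model_id())
  list(spec = spec, classes = cls, track = track, map = gen$recmap,
       b = b, b10 = aggregate_b(b, 10000))
})

## A model whose DDFEs are a point mass (closed-form checks).
point_mass_model <- function(s = 0.01, include_gc = FALSE) {
  m <- parse_model_id(if (include_gc) "M_LN,StdMut,CO+GC"
                      else "M_LN,StdMut,CO")
  m$ddfe_coding <- m$ddfe_noncoding <- ddfe("point_mass", mean_s = s)
  m$hybrid <- FALSE
  m
}

## Flat recombination map helper.
flat_map <- function(c_cM_Mb, length_bp = 1e6, chrom = "chrS",
                     window_bp = 1e5, ...) {
  start <- seq(0, length_bp - 1, by = window_bp)
  recmap(chrom, start, pmin(start + window_bp, length_bp),
         rep(c_cM_Mb, length(start)), ...)
}

## Join window diversity with a B landscape at matching windows.
join_b <- function(wd, landscape) {
  wd$B <- landscape$B[match(wd$start, landscape$start)]
  wd
}
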