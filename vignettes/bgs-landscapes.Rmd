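---
title: "Background-selection landscapes and diversity baselines with bgsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-selection landscapes and diversity baselines with bgsmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgsmap)
```

## The model

Background selection (BGS) is the reduction of neutral genetic diversity
caused by the continual removal of linked deleterious mutations. Its
strength at a focal neutral site is summarized by `B = pi / pi0`, the
expected diversity relative to what it would be under free recombination.
In the classical structured-coalescent approximation, a selected site `i`
with heterozygous effect `t_i = s_i h`, deleterious mutation rate `u_i`
(per haploid copy per generation) and recombination frequency `r_i` to the
focal site contributes

```
E_i = u_i * t_i / (t_i + r_i (1 - t_i))^2,      B = exp(-sum_i E_i).
```

At `r = 0` the contribution reduces to `u_i / (s_i h)`, so a fully linked
region with diploid deleterious rate `U` gives the familiar
`B = exp(-U / (2 s h))` (this is asserted in the test suite). Because
selection coefficients vary across mutations, the per-site term is
averaged over a distribution of deleterious fitness effects (DDFE)
`phi(s)`:

```
K(r) = E_phi[ s h / (s h + r (1 - s h))^2 ],
```

with two caveats that matter numerically:

* **Truncation.** Mutations with `s` below the effectively-neutral
  threshold `s_T ~ 1/Ne` drift as if neutral and generate no BGS. The
  DDFE is conditioned on `s >= s_T` and, in compensation, the deleterious
  mutation rate is multiplied by the retained mass
  (`effective_deleterious_rate()`). With `Ne = 1e6`, the log-normal DDFE
  loses 15.3% of its mass and the gamma 7.4% (18.6% and 9.1% on the X,
  where `s_X = (2/3) s_A` and the threshold satisfies
  `0.75 Ne s_X ~ 1`).
* **Lethals.** The heavy-tailed log-normal places mass above `s = 1`.
  Since `s` is a selection coefficient against homozygotes, that mass is
  clamped to `s = 1` inside the kernel integral rather than discarded: it
  represents lethal mutations, which still remove linked variation for
  the single generation they exist. The choice is numerically negligible
  (the mass is ~2% for the default log-normal and its `K` contribution is
  bounded by `1/h`), but it is made explicit here because the alternative
  (renormalizing it away) would slightly weaken predicted BGS.

### DDFE families and parameters

| family | parameters (defaults) | role |
|---|---|---|
| log-normal | median `s` = 2.31e-4, sd of `ln s` = 5.308 | default; heavy tails capture both effectively-neutral and lethal mutations |
| gamma | shape `k` = 0.3, mean `s` = 2.5e-3 | alternative with thinner tails, stronger BGS |
| point mass | single `s` | degenerate case with closed-form kernels, used by tests |

`sd_log` is the standard deviation of the *natural* logarithm of `s`;
only under that reading does the truncated mass reproduce the fractions
above, and a unit test pins the interpretation. Dominance is `h = 0.5`
throughout (genic selection); all selection parameters scale by `2/3` on
the X chromosome.

### Site classes and deleterious rates

Every base is classified (`classify_sites()`) as coding, UTR, intron,
intergenic or masked (TEs and repeats). Constrained-site counts per 1-kb
window follow fixed constraint fractions: nonsynonymous
`L_coding * 0.75 * 0.92`, UTR `* 0.81`, intron `* 0.56`, intergenic
`* 0.5`. Precedence among overlapping annotations is: masked beats
everything, coding (in any isoform) beats UTR, UTR beats intron, and a
base is called intronic only when it overlaps no other annotation —
intronic bases shadowed by an alternatively spliced exon are attributed
to that exon's class. This precedence is a package decision; annotations
rarely force the issue but it is tested explicitly.

The per-bp deleterious rate is `u = 8.4e-9` under the standard-mutation
models (`StdMut`, diploid `U = 1.2`, which folds in TE insertions) and
`4.2e-9` under `LowMut` (`U = 0.6`). The TE contribution can be derived
independently from mutation–selection balance
(`te_insertion_rate()`): a segregation probability of 633 exonic TEs per
21 Mb of exon, over 15 sampled chromosomes, with `s_h = 0.0025` gives
`u_TE ~ 5e-9` per bp — the arithmetic behind treating `U = 1.2` as the
TE-inclusive rate.

### Recombination

Crossover maps are windowed (100-kb resolution), in cM/Mb per female
meiosis. Between two sites `d` bp apart the package uses

```
r = sex_factor * [ d_CO(Morgans) + gamma * L_GC * (1 - exp(-d / L_GC)) ]
```

with gene-conversion initiation rate `gamma = 1.25e-7`/bp/female meiosis
and mean tract length `L_GC = 518` bp. The gene-conversion term is the
standard tract-overlap form: linear in `d` for `d << L_GC` and saturating
at `gamma * L_GC` — both limits are checked numerically. It is kept
pluggable (`gc_term`) so an alternative functional form can be swapped
without touching callers. `sex_factor` is 0.5 for autosomes and 0.66 for
the X (males do not recombine; 0.66 is used verbatim rather than 2/3).
Frequencies below 1e-10 are floored to zero and values are capped at 1.

Two further conventions matter:

* **Within-window linkage.** The landscape is computed at 1-kb
  resolution under the assumption that all sites within a 1-kb window are
  fully linked to each other and share a single recombination frequency
  with every other window (taken between window centers). This
  approximation lives in `pairwise_r()` itself, so every consumer —
  including the brute-force validation oracle — treats same-window pairs
  as `r = 0`. That placement is deliberate: the truncated-DDFE kernel
  rises steeply as `r -> 0` (mass piles up just above `s_T`, where
  `K(0) = E[1/(s h)]` is dominated by barely-selected mutations), so an
  oracle using exact intra-window distances would diverge from the
  windowed computation by tens of percent and would validate nothing
  about the implementation. With the convention shared, the residual
  cross-window discretization error is ~0.1% and the 1%-agreement check
  in the test suite is a genuine test of the kernel, grid and
  bookkeeping.
* **Trimming.** Chromosome arms can be trimmed of sub-telomeric and
  sub-centromeric low-recombination stretches: scanning inward from each
  end, the kept region starts at the first run of 3 consecutive 100-kb
  windows with `c > 1` cM/Mb. The kept region is assumed to begin at the
  run's first window (the alternative reading — detect the run, keep from
  the scan origin — would keep the low-recombination stretch itself,
  which contradicts the purpose of trimming).

### The kernel grid

`build_kernel()` evaluates `K(r)` by adaptive quadrature on the log-`s`
scale at 512 log-spaced grid points spanning `r` in `[1e-10, 1]`, plus
the exact `r = 0` value; evaluation elsewhere interpolates linearly in
`(ln r, ln K)`. The kernel is smooth and near power-law in `r`, so 512
points keep interpolation error well below the 1e-4 relative tolerance at
which the grid is tested against an independent dense-trapezoid
quadrature. Two-DDFE hybrid models (`M_LN/G`, `M_G/LN`) build one kernel
per site class; single-DDFE models share one kernel object.

`compute_B()` then sums, for every focal window, the constrained-site
loads of all windows weighted by the interpolated kernel — `O(W^2)`
kernel lookups per chromosome, vectorized in blocks. `oracle_B()` is the
deliberately naive counterpart: a double loop over focal positions and
individual base pairs with dense quadrature and no kernel grid, used only
on fixtures up to 200 kb.

### D_B quantiles: the genomic scale of BGS

For a focal window, `db_quantiles()` reports the size of the symmetric
physical interval (grown 1 kb per side per step) whose summed exponent
reaches 50/75/90% of the whole-chromosome exponent, in kb and in cM.
Symmetric physical growth is a package decision — the quantity is also
well-defined under greedy largest-contribution-first growth, but the
symmetric rule matches the "region around a focal point" reading and is
trivially reproducible.

## The diversity baseline and outlier scan

Silent diversity `pi_sil` is pairwise diversity per bp at intronic and
intergenic sites, computed per site with the unbiased `n/(n-1)`
correction using each site's own non-N sample size, requiring at least 10
non-N alleles per site; 1-kb and 10-kb windows additionally require more
than 500 and 1,000 silent sites respectively. Tajima's D per window is
normalized by the magnitude of its theoretical minimum for the same `n`
and number of segregating sites (all variants singletons), preserving
sign: `D_norm = D / |Dmin|`, so a fully singleton spectrum scores exactly
-1. (Strongly positive spectra can exceed +1 under this normalization;
the package does not clamp.) With variable per-site coverage the window
SFS uses the modal non-N sample size — exact for the synthetic fixtures,
an approximation for masked real data.

The baseline is an ordinary least-squares regression of window `pi_sil`
on `B`, fitted separately for autosomes and X so no X/A assumption enters
(the "generalized regression" is interpreted as OLS with intercept: the
residual-normality diagnostic below presupposes roughly normal residuals,
and `B` itself is the regressor since the fit absorbs the proportionality
constant `theta0`). Outliers are flagged from *externally* studentized
residuals (`pi_sil-R`; the tested window is excluded from its own error
estimate) with two-sided `t` P values on `n - 3` degrees of freedom —
deficits (sweep-like) and excesses (balancing-like) at nominal
`P < 0.05`, with Benjamini–Hochberg control reported at FDR 0.10.
Two-sided P values are used throughout; flags then split by residual
sign. A chi-square goodness-of-fit over 24 equal-probability normal bins
(df = 23) checks that the residual distribution is compatible with the
normal assumption.

## Efficacy-of-selection correlates

Per-gene `dN`, `dS` and `omega = dN/dS` are consumed as a precomputed
table (codon-model fitting is out of scope). Genes are filtered — CDS
< 450 bp, < 100 aligned amino acids, premature stops, positive-selection
q < 0.05, `omega > 0.75` — and `omega_R` is the residual of `omega` on
`dS` (per chromosome group), removing both weak selection on synonymous
sites and coalescent-depth variation. `correlate_b_omega()` reports
Spearman correlations between `omega_R` and `B`, with gene-level B looked
up at the CDS midpoint (a package decision; a gene-span average is the
obvious alternative and midpoints of compact genes make the difference
negligible) or averaged in 100-kb windows.

## What the synthetic generator emulates — and what it does not

`generate_genome()` tiles a chromosome with identical genes (1-kb 5'UTR,
300-bp exon, 1-kb intron, 600-bp exon, 200-bp intron, 600-bp exon,
300-bp 3'UTR; intergenic fills the 10-kb tile), places a few 500-bp TEs
in intergenic DNA, and writes a windowed crossover map (default: 100-kb
windows alternating 3.5/0.5 cM/Mb; constant and two-block profiles are
available). `generate_polymorphism()` places segregating variants at
silent sites so each window's *expected* per-site diversity is
`theta0 * B` (default `theta0 = 0.01`, 15 haplotypes), with a neutral
`1/k` frequency spectrum; planted sweeps multiply expected diversity
(default fixtures use 0.2x) and skew the spectrum toward singletons,
planted balanced regions (3x) concentrate variants at intermediate
frequencies. Under the `1/k` spectrum the expected Tajima's D is zero by
construction, which the suite verifies.

This generator tests the *inference contract* — that the pipeline
recovers `theta0` as the regression slope, flags planted departures with
the right sign, and keeps false positives at the nominal rate. It is not
a population-genetic simulation: sites are independent (no linkage
disequilibrium), the SFS shapes are parametric tilts rather than
coalescent outcomes, coverage is uniform, and `B` enters as the truth
rather than as an emergent property. Passing tests therefore demonstrate
correctness of the computation and the detection machinery, not that BGS
explains any particular dataset.

One consequence of the periodic gene layout is worth stating. Across
models that differ in DDFE family, rank agreement of `B` landscapes on
the tiled 1-Mb fixture reaches Spearman rho ~ 0.95 (exactly 1.0 between
models differing only in mutation rate, whose exponents are proportional)
— lower than the near-perfect concordance seen on real genomes, where
shared gene-density and recombination variance at the cM scale dominates
every model's ranking. The periodic fixture has no such shared
large-scale variance, so near-tied windows reorder freely under
family-specific kernel shapes; the corresponding acceptance check is
reported as measured rather than relaxed.

## Fixture sizes and numerical choices

Desk-scale problem sizes were chosen so the full suite runs in minutes:
a 100-kb / 10-gene chromosome for oracle comparisons (the per-bp oracle
is quadratic), the 1-Mb / 100-gene genome for parameter recovery and
rank checks, and a 3-Mb / 300-gene genome scanned in 10-kb windows for
outlier power. The last size comes from a power calculation rather than
convenience: with only ~100 scan windows the six planted windows
contaminate the OLS fit and inflate the residual scale roughly
three-fold, masking a 0.2x sweep deficit (z ~ 1.5); at ~300 windows the
deficit stands at z ~ 2.4 per window and a three-window region is
recovered with >= 95% probability, matching the genome-scale regime the
scan is designed for (tens of thousands of windows). A 1-kb scan is
noise-limited for deficit detection at any genome size — a window of
~700 silent sites with expected diversity 0.004 carries binomial noise of
the same order as the signal — which is why coarser windows are the
default for outlier scanning.

Other numerical choices: quadrature is adaptive (`rel.tol = 1e-9`) on
the log-`s` scale where the integrand is smooth; the oracle uses 300
trapezoid nodes plus a lethal-mass node; coordinates are 0-based
half-open internally and converted at I/O boundaries; degenerate inputs
(zero selected sites, constant `B`, perfect fits, empty windows,
monomorphic alignments) are handled explicitly and tested.

## Known limitations

* The structured-coalescent exponent overstates BGS for weakly selected
  mutations at very low recombination (`s` near `s_T`, `r` near 0);
  truncation bounds but does not remove this, and the within-window
  linkage convention inherits it. This is a property of the model family,
  shared with the computation it reproduces.
* Tajima's D with heterogeneous per-site coverage uses a single modal
  `n` per window.
* The outlier scan assumes homoscedastic residuals; windows with few
  silent sites are noisier than the fit assumes, which the silent-site
  thresholds mitigate but do not eliminate.
* X-chromosome handling adjusts selection scale, threshold and sex
  factor, but the synthetic generator emits autosomal fixtures only;
  X-specific code paths are exercised at the unit level.
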