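## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic test genome
#'
#' Describes a single synthetic chromosome emulating the structure the
#' analysis assumes: evenly spaced genes with a typical Drosophila
#' geometry (1-kb 5'UTR, 300-bp exon, 1-kb intron, 600-bp exon, 200-bp
#' intron, 600-bp exon, 300-bp 3'UTR; intergenic sequence fills each
#' tile), a windowed crossover map, and polymorphism whose expected window
#' diversity is `theta0 * B`, optionally perturbed by planted sweep
#' (diversity deficit, singleton-skewed) or balancing (excess,
#' intermediate-frequency) features.
#'
#' @param seed integer seed; all generators are reproducible from it.
#' @param chromosome_length chromosome length in bp (default 1 Mb).
#' @param n_genes number of genes, evenly tiled (default 100).
#' @param chromosome chromosome name.
#' @param crossover_profile `"hot_cold"` (alternating 100-kb windows of
#'   `c_low`/`c_high`), `"piecewise"` (low half, high half) or
#'   `"constant"`.
#' @param c_cM_Mb constant crossover rate (constant profile).
#' @param c_low,c_high rates for the structured profiles.
#' @param theta0 baseline silent diversity per bp in the absence of BGS.
#' @param n_haplotypes sampled haplotypes (default 15).
#' @param n_tes transposable elements placed in intergenic sequence.
#' @param planted_features `NULL` or data.frame with columns `pos` (start
#'   bp), `span` (bp), `kind` (`"sweep"`/`"balanced"`), `multiplier`.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1, chromosome_length = 1e6, n_genes = 100,
                           chromosome = "chrS",
                           crossover_profile = c("hot_cold", "piecewise",
                                                 "constant"),
                           c_cM_Mb = 2, c_low = 0.5, c_high = 3.5,
                           theta0 = 0.01, n_haplotypes = 15,
                           n_tes = n_genes %/% 10,
                           planted_features = NULL) {
  crossover_profile <- match.arg(crossover_profile)
  if (chromosome_length <= 0 || theta0 < 0 || n_haplotypes < 4)
    stop("invalid spec: positive length, theta0 >= 0, >= 4 haplotypes")
  gene_bp <- 4000
  if (n_genes > 0 && chromosome_length / n_genes < gene_bp)
    stop("gene geometry (4 kb) exceeds the per-gene tile")
  if (!is.null(planted_features)) {
    stopifnot(all(c("pos", "span", "kind", "multiplier") %in%
                    names(planted_features)))
    if (any(planted_features$pos + planted_features$span >
            chromosome_length))
      stop("planted feature extends beyond the chromosome")
    if (!all(planted_features$kind %in% c("sweep", "balanced")))
      stop("feature kind must be 'sweep' or 'balanced'")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic annotation, TE track and recombination map
#'
#' Writes a GFF3 gene annotation (via `rtracklayer`), a BED TE track and a
#' windowed crossover-map TSV that parse cleanly through
#' [classify_sites()] and [read_recmap()]. Deterministic given the spec
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return list with paths `gff3`, `te_bed`, `recmap_tsv`, and the
#'   in-memory `recmap` object.
#' @export
generate_genome <- function(spec, dir = tempfile("syngenome")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- spec$chromosome
  L <- spec$chromosome_length
  tile <- if (spec$n_genes > 0) L %/% spec$n_genes else L

  feats <- list()
  add <- function(start0, end0, type, id, parent = NULL) {
    feats[[length(feats) + 1L]] <<- data.frame(
      start = start0 + 1, end = end0, type = type, ID = id,
      Parent = if (is.null(parent)) NA_character_ else parent,
      stringsAsFactors = FALSE)
  }
  if (spec$n_genes > 0) {
    for (g in seq_len(spec$n_genes)) {
      S <- (g - 1) * tile
      gid <- sprintf("gene%04d", g); mid <- sprintf("mRNA%04d", g)
      add(S, S + 4000, "gene", gid)
      add(S, S + 4000, "mRNA", mid, gid)
      add(S, S + 1000, "five_prime_UTR", sprintf("%s.utr5", mid), mid)
      add(S + 1000, S + 1300, "CDS", sprintf("%s.cds1", mid), mid)
      add(S + 2300, S + 2900, "CDS", sprintf("%s.cds2", mid), mid)
      add(S + 3100, S + 3700, "CDS", sprintf("%s.cds3", mid), mid)
      add(S + 3700, S + 4000, "three_prime_UTR", sprintf("%s.utr3", mid), mid)
      add(S, S + 1300, "exon", sprintf("%s.ex1", mid), mid)
      add(S + 2300, S + 2900, "exon", sprintf("%s.ex2", mid), mid)
      add(S + 3100, S + 4000, "exon", sprintf("%s.ex3", mid), mid)
    }
  }
  gff_path <- file.path(dir, "annotation.gff3")
  te_path <- file.path(dir, "tes.bed")
  map_path <- file.path(dir, "recmap.tsv")

  if (length(feats)) {
    tab <- do.call(rbind, feats)
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(tab$start, tab$end), strand = "+",
      type = tab$type, ID = tab$ID,
      phase = ifelse(tab$type == "CDS", 0L, NA_integer_),
      Parent = ifelse(is.na(tab$Parent), "", tab$Parent))
    gr$Parent <- S4Vectors::unname(
      IRanges::CharacterList(ifelse(tab$Parent == "" | is.na(tab$Parent),
                                    list(character(0)), as.list(tab$Parent))))
    rtracklayer::export(gr, gff_path, format = "gff3")
  } else {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", chrom, L)), gff_path)
  }

  ## TEs: fixed-width insertions placed deterministically in intergenic DNA
  te <- with_seed(spec$seed + 1L, {
    if (spec$n_tes > 0 && spec$n_genes > 0) {
      tiles <- sample(seq_len(spec$n_genes), spec$n_tes,
                      replace = spec$n_tes > spec$n_genes)
      start0 <- (tiles - 1) * tile + 4000 +
        floor(stats::runif(spec$n_tes, 0, tile - 4000 - 500))
      data.frame(start = start0, end = start0 + 500)
    } else data.frame(start = numeric(0), end = numeric(0))
  })
  writeLines(sprintf("%s\t%d\t%d\tTE%03d", chrom, as.integer(te$start),
                     as.integer(te$end), seq_len(nrow(te))), te_path)

  wb <- min(1e5, L)
  wstart <- seq(0, L - 1, by = wb)
  wend <- pmin(wstart + wb, L)
  cvals <- switch(spec$crossover_profile,
    constant = rep(spec$c_cM_Mb, length(wstart)),
    piecewise = ifelse(wstart < L / 2, spec$c_low, spec$c_high),
    hot_cold = ifelse(seq_along(wstart) %% 2 == 1, spec$c_high, spec$c_low))
  utils::write.table(
    data.frame(chrom = chrom, start = wstart, end = wend,
               c_cM_Mb = cvals),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(gff3 = gff_path, te_bed = te_path, recmap_tsv = map_path,
       recmap = recmap(chrom, wstart, wend, cvals))
}

## SFS weights over derived counts 1..n-1 for each feature kind.
sfs_weights <- function(kind, n) {
  k <- seq_len(n - 1)
  switch(kind,
    neutral = 1 / k,
    sweep = { w <- 1 / k; w[1] <- w[1] * 20; w },  # singleton-skewed
    balanced = stats::dnorm(k, n / 2, n / 8))      # intermediate-frequency
}

#' Generate polymorphism whose expected diversity follows theta0 * B
#'
#' Places segregating variants at silent (intron + intergenic) sites so
#' that each window's expected per-site diversity equals
#' `theta0 * B * multiplier`, with binomial sampling noise given the
#' haplotype count. Planted sweep features reduce diversity and skew the
#' frequency spectrum toward singletons; balancing features increase
#' diversity with intermediate-frequency variants. Non-silent sites are
#' left monomorphic (they never enter silent-diversity estimation).
#'
#' @param landscape a 1-kb `b_landscape` for the synthetic chromosome.
#' @param classes a [classify_sites()] result for the same chromosome.
#' @param spec the [synthetic_spec()] (seed, theta0, haplotypes, features).
#' @param seed optional override of `spec$seed` (replicate index).
#' @return list of class `"synthetic_polymorphism"`: `sites` (data.frame
#'   `pos`, `n`, `derived` for segregating sites), `n_haplotypes`,
#'   `multiplier` (per 1-kb window), and the spec.
#' @export
generate_polymorphism <- function(landscape, classes, spec,
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(classes, "site_classes"))
  n <- spec$n_haplotypes
  L <- classes$length
  W <- nrow(landscape)
  if (max(landscape$end) < L) stop("B landscape does not cover the chromosome")

  mult <- rep(1, W)
  kind <- rep("neutral", W)
  pf <- spec$planted_features
  if (!is.null(pf)) for (i in seq_len(nrow(pf))) {
    w <- which(landscape$start >= pf$pos[i] &
               landscape$end <= pf$pos[i] + pf$span[i])
    mult[w] <- pf$multiplier[i]
    kind[w] <- pf$kind[i]
  }
  p_window <- spec$theta0 * landscape$B * mult
  if (any(p_window > 0.5))
    stop("theta0 * multiplier implies per-bp diversity > 0.5")

  pi_k <- 2 * seq_len(n - 1) * (n - seq_len(n - 1)) / (n * (n - 1))
  ew <- lapply(c("neutral", "sweep", "balanced"), function(kd) {
    w <- sfs_weights(kd, n)
    list(w = w / sum(w), epi = sum(w / sum(w) * pi_k))
  })
  names(ew) <- c("neutral", "sweep", "balanced")

  silent_pos <- which(classes$labels == 3L | classes$labels == 4L)
  win_of <- (silent_pos - 1L) %/% (landscape$end[1] - landscape$start[1]) + 1L
  epi_by_kind <- vapply(ew, `[[`, numeric(1), "epi")
  q_site <- p_window[win_of] / epi_by_kind[kind[win_of]]
  if (any(q_site > 1)) stop("segregation probability exceeds 1; lower theta0")

  sites <- with_seed(seed, {
    seg <- stats::runif(length(silent_pos)) < q_site
    pos <- silent_pos[seg]
    kd <- kind[win_of[seg]]
    der <- integer(length(pos))
    for (k in c("neutral", "sweep", "balanced")) {
      i <- kd == k
      if (any(i))
        der[i] <- sample.int(n - 1, sum(i), replace = TRUE,
                             prob = ew[[k]]$w)
    }
    data.frame(pos = pos, n = rep.int(n, length(pos)), derived = der)
  })
  structure(list(sites = sites, n_haplotypes = n, multiplier = mult,
                 kind = kind, spec = spec), class = "synthetic_polymorphism")
}

#' Write a synthetic polymorphism sample as a FASTA alignment
#'
#' Expands the segregating-site table to `n_haplotypes` full-length
#' sequences (reference base `A`, derived base `G`), assigning the derived
#' allele to a seeded random subset of haplotypes per site.
#'
#' @param poly a [generate_polymorphism()] result.
#' @param length_bp chromosome length.
#' @param path output FASTA path.
#' @param seed seed for haplotype assignment.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(poly, length_bp, path,
                                  seed = poly$spec$seed) {
  n <- poly$n_haplotypes
  m <- matrix("A", nrow = n, ncol = length_bp)
  with_seed(seed + 2L, {
    for (i in seq_len(nrow(poly$sites))) {
      carriers <- sample.int(n, poly$sites$derived[i])
      m[carriers, poly$sites$pos[i]] <- "G"
    }
  })
  seqs <- Biostrings::DNAStringSet(apply(m, 1, paste0, collapse = ""))
  names(seqs) <- sprintf("hap%02d", seq_len(n))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Generate a synthetic per-gene molecular-evolution table
#'
#' Emits one record per gene with `dS` drawn with positive mean and
#' `omega = baseline + slope_dS * dS - effect_size * B + noise`, so that
#' after controlling for `dS` the residual `omega_R` is anticorrelated
#' with B when `effect_size > 0`. A configurable fraction of genes violate
#' the inclusion filters (short CDS, sparse alignment, premature stop,
#' positive selection, high omega), spread evenly over the five rules.
#'
#' @param landscape a `b_landscape` for the synthetic chromosome.
#' @param spec a [synthetic_spec()].
#' @param effect_size nonnegative coefficient of B in omega (default 0.02).
#' @param baseline,slope_dS,noise_sd remaining generative parameters.
#' @param violation_rate fraction of genes planted as filter violations.
#' @param seed optional override of `spec$seed`.
#' @return data.frame gene table (see [filter_genes()] for columns), with
#'   a logical `planted_violation` audit column.
#' @export
generate_gene_table <- function(landscape, spec, effect_size = 0.02,
                                baseline = 0.15, slope_dS = 0.3,
                                noise_sd = 0.02, violation_rate = 0,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (violation_rate < 0 || violation_rate > 1)
    stop("violation_rate must lie in [0, 1]")
  ng <- spec$n_genes
  tile <- spec$chromosome_length %/% ng
  mid <- (seq_len(ng) - 1) * tile + 2000
  B <- landscape$B[findInterval(mid, landscape$start)]
  with_seed(seed + 3L, {
    dS <- stats::rgamma(ng, shape = 4, rate = 40)     # mean 0.1
    omega <- pmax(baseline + slope_dS * dS - effect_size * B +
                    stats::rnorm(ng, 0, noise_sd), 1e-4)
    d <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(ng)),
      chromosome = spec$chromosome, midpoint = mid, group = "autosome",
      cds_length_bp = 1500L, aligned_aa = 450L,
      dS = dS, dN = omega * dS, omega = omega,
      premature_stop = FALSE, positive_selection_q = 1,
      planted_violation = FALSE)
    nv <- round(violation_rate * ng)
    if (nv > 0) {
      v <- sample.int(ng, nv)
      rule <- rep_len(1:5, nv)
      d$cds_length_bp[v[rule == 1]] <- 300L
      d$aligned_aa[v[rule == 2]] <- 50L
      d$premature_stop[v[rule == 3]] <- TRUE
      d$positive_selection_q[v[rule == 4]] <- 0.01
      d$omega[v[rule == 5]] <- 0.9
      d$planted_violation[v] <- TRUE
    }
    d
  })
}
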