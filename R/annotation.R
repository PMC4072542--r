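#' Site-class constraint configuration
#'
#' Fractions of sites per annotation class treated as constrained (under
#' purifying selection strong enough to matter for BGS), plus the fraction
#' of coding sites that are nonsynonymous.
#'
#' @param cs_nonsyn constrained fraction of nonsynonymous sites (0.92).
#' @param cs_utr constrained fraction of UTR sites (0.81).
#' @param cs_intron constrained fraction of intronic sites (0.56).
#' @param cs_intergenic constrained fraction of intergenic sites (0.5).
#' @param coding_nonsyn_fraction fraction of coding sites that alter the
#'   amino-acid sequence (0.75).
#' @return list of class `"site_class_config"`.
#' @export
site_class_config <- function(cs_nonsyn = 0.92, cs_utr = 0.81,
                              cs_intron = 0.56, cs_intergenic = 0.5,
                              coding_nonsyn_fraction = 0.75) {
  v <- c(cs_nonsyn, cs_utr, cs_intron, cs_intergenic, coding_nonsyn_fraction)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("all site-class fractions must lie in [0, 1]")
  structure(list(cs_nonsyn = cs_nonsyn, cs_utr = cs_utr,
                 cs_intron = cs_intron, cs_intergenic = cs_intergenic,
                 coding_nonsyn_fraction = coding_nonsyn_fraction),
            class = "site_class_config")
}

SITE_LEVELS <- c("coding", "utr", "intron", "intergenic", "masked")

#' Classify every base of a chromosome into site classes
#'
#' Assigns exactly one label per base from `coding`, `utr`, `intron`,
#' `intergenic`, `masked`. Precedence: a base inside a TE or repeat is
#' masked; a base coding in any transcript is coding; UTR beats intron;
#' intronic bases are labelled `intron` only where they overlap no other
#' annotation (alternatively spliced exons, other genes, TEs); everything
#' between gene models is intergenic. Genic bases that fall in none of the
#' above (e.g. intron bases shadowed by a non-CDS, non-UTR exon) are
#' masked, i.e. excluded from all counts.
#'
#' @param gff3 path to a GFF3 file with gene/mRNA/exon/CDS/UTR features, or
#'   a `GRanges` already imported.
#' @param te_bed,repeat_bed optional BED paths (or `GRanges`) of
#'   transposable elements and repeats to mask.
#' @param chromosome chromosome to classify (default: the first seqname).
#' @param chrom_length chromosome length in bp; default: the maximum
#'   annotated end coordinate.
#' @return object of class `"site_classes"`: list with `chromosome`,
#'   `length`, and `labels` (integer vector, indices into `levels`).
#' @export
classify_sites <- function(gff3, te_bed = NULL, repeat_bed = NULL,
                           chromosome = NULL, chrom_length = NULL) {
  gr <- if (methods::is(gff3, "GRanges")) gff3 else rtracklayer::import(gff3)
  if (length(gr) == 0L) {
    ## gene-free annotation: everything is intergenic (minus masks)
    if (is.null(chromosome) && is.character(gff3)) {
      sr <- grep("^##sequence-region", readLines(gff3, n = 50), value = TRUE)
      if (length(sr)) chromosome <- strsplit(sr[1], "\\s+")[[1]][2]
    }
    if (is.null(chromosome) || is.null(chrom_length))
      stop("empty annotation: chromosome and chrom_length are required")
    labels <- rep.int(4L, chrom_length)
    ib <- function(x) {
      if (is.null(x)) return(IRanges::IRanges())
      b <- if (methods::is(x, "GRanges")) x else rtracklayer::import(x)
      IRanges::reduce(IRanges::ranges(
        b[as.character(GenomicRanges::seqnames(b)) == chromosome]))
    }
    mask <- IRanges::restrict(IRanges::union(ib(te_bed), ib(repeat_bed)),
                              start = 1L, end = chrom_length)
    for (k in seq_along(mask))
      labels[IRanges::start(mask)[k]:IRanges::end(mask)[k]] <- 5L
    return(structure(list(chromosome = chromosome, length = chrom_length,
                          labels = labels, levels = SITE_LEVELS),
                     class = "site_classes"))
  }
  if (is.null(chromosome))
    chromosome <- as.character(GenomicRanges::seqnames(gr)[1])
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chromosome]
  if (length(gr) == 0L) stop("no annotation on chromosome ", chromosome)
  type <- as.character(gr$type)
  if (is.null(chrom_length)) chrom_length <- max(GenomicRanges::end(gr))

  mrna <- gr[type %in% c("mRNA", "transcript")]
  if (length(mrna)) {
    par <- as.character(unlist(mrna$Parent))
    for (g in unique(par)) {
      st <- unique(as.character(GenomicRanges::strand(mrna[par == g])))
      if (length(setdiff(st, "*")) > 1L)
        stop("strand-inconsistent gene model: ", g)
    }
  }

  rng <- function(x) IRanges::reduce(IRanges::ranges(x))
  cds <- rng(gr[type == "CDS"])
  utr <- rng(gr[type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")])
  exons <- rng(gr[type == "exon"])
  tx <- rng(if (length(mrna)) mrna else gr[type == "gene"])
  introns <- IRanges::setdiff(tx, IRanges::union(exons, IRanges::union(cds, utr)))

  import_bed <- function(x) {
    if (is.null(x)) return(IRanges::IRanges())
    b <- if (methods::is(x, "GRanges")) x else rtracklayer::import(x)
    b <- b[as.character(GenomicRanges::seqnames(b)) == chromosome]
    IRanges::reduce(IRanges::ranges(b))
  }
  mask <- IRanges::union(import_bed(te_bed), import_bed(repeat_bed))

  ## introns only where they overlap no other annotation
  other <- Reduce(IRanges::union, list(exons, cds, utr, mask))
  clean_introns <- IRanges::setdiff(introns, other)
  ## genic leftovers (in a transcript but in no clean class) -> masked
  genic_leftover <- IRanges::setdiff(
    tx, Reduce(IRanges::union, list(cds, utr, clean_introns)))

  labels <- rep.int(4L, chrom_length)            # intergenic
  paint <- function(labels, ir, code) {
    ir <- IRanges::restrict(ir, start = 1L, end = chrom_length)
    for (k in seq_along(ir))
      labels[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- code
    labels
  }
  labels <- paint(labels, clean_introns, 3L)
  labels <- paint(labels, utr, 2L)
  labels <- paint(labels, cds, 1L)
  labels <- paint(labels, genic_leftover, 5L)
  labels <- paint(labels, mask, 5L)

  structure(list(chromosome = chromosome, length = chrom_length,
                 labels = labels, levels = SITE_LEVELS),
            class = "site_classes")
}

#' @export
print.site_classes <- function(x, ...) {
  tab <- tabulate(x$labels, 5L)
  cat(sprintf("Site classes for %s (%d bp):\n", x$chromosome, x$length))
  for (k in 1:5)
    cat(sprintf("  %-10s %10d bp (%.1f%%)\n", x$levels[k], tab[k],
                100 * tab[k] / x$length))
  invisible(x)
}

#' Per-window counts of constrained (BGS-relevant) sites
#'
#' Aggregates per-bp site classes into 1-kb windows and applies the
#' constraint fractions: `Naa = coding_bp * 0.75 * cs_nonsyn`,
#' `Nutr_ss = utr_bp * cs_utr + intron_bp * cs_intron`,
#' `Nnc_ss = intergenic_bp * cs_intergenic`. Masked bases count nowhere.
#'
#' @param classes a [classify_sites()] result.
#' @param config a [site_class_config()].
#' @param window_bp window size in bp (default 1000).
#' @return data.frame of class `"selected_track"` with per-window bp counts
#'   per class, the constrained-site counts, and `n_silent_candidate`
#'   (intron + intergenic bp available for diversity estimation).
#' @export
count_selected_sites <- function(classes, config = site_class_config(),
                                 window_bp = 1000) {
  stopifnot(inherits(classes, "site_classes"),
            inherits(config, "site_class_config"))
  L <- classes$length
  win <- (seq_len(L) - 1L) %/% window_bp
  nw <- max(win) + 1L
  bp <- vapply(1:5, function(k)
    as.vector(rowsum((classes$labels == k) + 0, win, reorder = TRUE)),
    numeric(nw))
  if (is.null(dim(bp))) bp <- matrix(bp, nrow = 1L)
  out <- data.frame(
    chromosome = classes$chromosome,
    start = (seq_len(nw) - 1L) * window_bp,
    end = pmin(seq_len(nw) * window_bp, L),
    coding_bp = bp[, 1], utr_bp = bp[, 2], intron_bp = bp[, 3],
    intergenic_bp = bp[, 4], masked_bp = bp[, 5])
  out$Naa <- out$coding_bp * config$coding_nonsyn_fraction * config$cs_nonsyn
  out$Nutr_ss <- out$utr_bp * config$cs_utr + out$intron_bp * config$cs_intron
  out$Nnc_ss <- out$intergenic_bp * config$cs_intergenic
  out$n_silent_candidate <- out$intron_bp + out$intergenic_bp
  class(out) <- c("selected_track", "data.frame")
  out
}
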