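#' Read an N-masked population alignment from FASTA
#'
#' One sequence per sampled haplotype, all of equal length, aligned to the
#' reference coordinate system. Returns an uppercase character matrix
#' (haplotypes x positions).
#'
#' @param path FASTA path.
#' @return character matrix with rownames from the FASTA headers.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("alignment sequences differ in length")
  m <- as.matrix(seqs)
  toupper(m)
}

#' Per-site pairwise diversity
#'
#' For one alignment column, the average number of pairwise differences
#' among non-N alleles with the small-sample correction `n/(n-1)`:
#' `pi = n/(n-1) * (1 - sum_a f_a^2)`. Columns with fewer than
#' `min_coverage` non-N alleles are missing.
#'
#' @param alleles character vector of alleles from `{A, C, G, T, N}`.
#' @param min_coverage minimum non-N alleles required (default 10).
#' @return per-site diversity, or `NA` if coverage is insufficient.
#' @export
per_site_pi <- function(alleles, min_coverage = 10) {
  a <- alleles[alleles != "N" & alleles != "-"]
  n <- length(a)
  if (n < max(min_coverage, 2L)) return(NA_real_)
  f <- table(a) / n
  (n / (n - 1)) * (1 - sum(f^2))
}

## Vectorized per-site pi and coverage over an alignment matrix.
alignment_site_stats <- function(aln) {
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(aln == b),
                   numeric(ncol(aln)))
  n <- rowSums(counts)
  sum_sq <- rowSums(counts * (counts - 1))       # sum n_a (n_a - 1)
  pi <- ifelse(n >= 2, 1 - sum_sq / (n * (n - 1)), NA_real_)
  ## 1 - sum f^2 corrected: n/(n-1) (1 - sum (n_a/n)^2) = 1 - sum n_a(n_a-1)/(n(n-1))
  seg <- rowSums(counts > 0) > 1
  derived <- ifelse(seg, n - apply(counts, 1, max), 0L)
  list(n = n, pi = pi, segregating = seg, minor_count = derived)
}

#' Windowed silent diversity from a masked alignment or site table
#'
#' Aggregates per-site pairwise diversity over silent sites (intronic and
#' intergenic, per the site classification) in non-overlapping windows.
#' Windows with too few analyzable silent sites are flagged excluded
#' (defaults: > 500 silent sites at 1-kb scale, > 1000 at 10-kb scale).
#' Tajima's D, normalized by its minimum (see [tajima_d_normalized()]), is
#' computed from each window's segregating-site frequency spectrum.
#'
#' @param x either a character alignment matrix (see [read_alignment()]) or
#'   a site table `data.frame` with columns `pos` (1-based), `n` (non-N
#'   alleles), `derived` (derived/minor allele count), covering segregating
#'   sites; monomorphic coverage is then assumed complete at `n_total`.
#' @param classes a [classify_sites()] result on the same coordinates.
#' @param window_bp window size (default 1000).
#' @param min_coverage minimum non-N alleles per site (default 10).
#' @param min_silent minimum silent sites for a window to be included;
#'   default 500 for 1-kb windows, 1000 for 10-kb, otherwise half the
#'   window size scaled accordingly.
#' @param n_total haplotype count (site-table input only).
#' @return data.frame of class `"window_diversity"`: per window `pi_sil`,
#'   `pi_intron`, `pi_intergenic`, `n_silent_sites`, `n_seg_sites`,
#'   `tajima_d_norm`, `included`.
#' @export
window_diversity <- function(x, classes, window_bp = 1000,
                             min_coverage = 10, min_silent = NULL,
                             n_total = NULL) {
  stopifnot(inherits(classes, "site_classes"))
  L <- classes$length
  if (is.null(min_silent))
    min_silent <- if (window_bp <= 1000) 500
                  else if (window_bp <= 10000) 1000
                  else 0
  lab <- classes$labels
  silent <- lab == 3L | lab == 4L

  if (is.matrix(x)) {
    if (ncol(x) != L) stop("alignment length does not match classification")
    st <- alignment_site_stats(x)
    n_site <- st$n
    pi_site <- ifelse(n_site >= min_coverage, st$pi, NA_real_)
    seg <- st$segregating & !is.na(pi_site)
    seg_pos <- which(seg & silent)
    seg_n <- n_site[seg_pos]
    seg_der <- st$minor_count[seg_pos]
  } else {
    if (is.null(n_total)) stop("n_total is required for site-table input")
    if (nrow(x) && max(x$pos) > L) stop("site table extends beyond classification")
    n_site <- rep.int(n_total, L)
    pi_vals <- numeric(L)
    ok <- x$n >= min_coverage
    n_site[x$pos] <- x$n
    k <- x$derived
    pi_vals[x$pos[ok]] <- (k * (x$n - k) * 2 / (x$n * (x$n - 1)))[ok]
    pi_site <- ifelse(n_site >= min_coverage, pi_vals, NA_real_)
    seg_pos <- x$pos[ok & x$derived > 0 & silent[x$pos]]
    seg_n <- x$n[ok & x$derived > 0 & silent[x$pos]]
    seg_der <- x$derived[ok & x$derived > 0 & silent[x$pos]]
  }

  usable <- silent & !is.na(pi_site)
  win <- (seq_len(L) - 1L) %/% window_bp
  nw <- max(win) + 1L
  agg <- function(v, w = win) as.vector(rowsum(v, w, reorder = TRUE))
  n_sil <- agg(usable + 0)
  sum_pi <- agg(ifelse(usable, pi_site, 0))
  intron_ok <- usable & lab == 3L
  inter_ok <- usable & lab == 4L
  n_int <- agg(intron_ok + 0); s_int <- agg(ifelse(intron_ok, pi_site, 0))
  n_itg <- agg(inter_ok + 0);  s_itg <- agg(ifelse(inter_ok, pi_site, 0))

  seg_win <- (seg_pos - 1L) %/% window_bp
  n_seg <- tabulate(seg_win + 1L, nbins = nw)
  taj <- rep(NA_real_, nw)
  if (length(seg_pos)) {
    for (w in unique(seg_win)) {
      i <- seg_win == w
      taj[w + 1L] <- tajima_d_normalized(
        n = as.integer(stats::median(seg_n[i])),
        sfs_counts = tabulate(seg_der[i],
                              nbins = max(seg_der[i])))
    }
  }

  out <- data.frame(
    chromosome = classes$chromosome,
    start = (seq_len(nw) - 1L) * window_bp,
    end = pmin(seq_len(nw) * window_bp, L),
    pi_sil = ifelse(n_sil > 0, sum_pi / n_sil, NA_real_),
    pi_intron = ifelse(n_int > 0, s_int / n_int, NA_real_),
    pi_intergenic = ifelse(n_itg > 0, s_itg / n_itg, NA_real_),
    n_silent_sites = n_sil,
    n_seg_sites = n_seg,
    tajima_d_norm = taj,
    included = n_sil > min_silent)
  class(out) <- c("window_diversity", "data.frame")
  out
}

#' Tajima's D normalized by its minimum
#'
#' Standard Tajima's D from the number of segregating sites `S` and mean
#' pairwise diversity, divided by the absolute value of `Dmin` -- the D
#' obtained for the same `n` and `S` when every variant is a singleton --
#' so excess rare variants push the statistic toward -1 while the sign of
#' D is preserved.
#'
#' @param n number of sequences (>= 4).
#' @param sfs_counts counts of derived-allele classes: `sfs_counts[k]` is
#'   the number of sites with derived (or minor, if folded) allele count
#'   `k`; folded spectra are handled identically since `pi` depends on
#'   `k (n - k)` only.
#' @return `D / |Dmin|`, or `NA` if there are no segregating sites.
#' @export
tajima_d_normalized <- function(n, sfs_counts) {
  if (n < 4) stop("need at least 4 sequences")
  S <- sum(sfs_counts)
  if (S == 0) return(NA_real_)
  k <- seq_along(sfs_counts)
  pi_total <- sum(sfs_counts * k * (n - k) * 2 / (n * (n - 1)))
  D <- tajima_d_raw(n, S, pi_total)
  Dmin <- tajima_d_raw(n, S, S * 2 / n)     # all singletons
  D / abs(Dmin)
}

## Textbook Tajima's D from n, S and total pairwise diversity.
tajima_d_raw <- function(n, S, pi_total) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
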