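#' Windowed recombination map
#'
#' A crossover map at fixed window resolution (100 kb in the source maps)
#' together with the gene-conversion model and the sex-averaging factor.
#' Crossover rates `c` are in cM/Mb per female meiosis. Gene conversion is
#' modelled as initiation rate `gamma_gc` per bp per female meiosis with
#' mean tract length `L_gc` bp. Because male Drosophila do not recombine,
#' realized recombination is `0.5 r` on autosomes and `0.66 r` on the X.
#'
#' @param chromosome chromosome identifier.
#' @param start,end window boundaries in bp (0-based half-open, contiguous).
#' @param c_cM_Mb crossover rate per window, cM/Mb per female meiosis.
#' @param gamma_gc gene-conversion initiation rate (/bp/female meiosis).
#' @param L_gc mean gene-conversion tract length (bp).
#' @param sex_factor 0.5 for autosomes, 0.66 for the X chromosome.
#' @return object of class `"recmap"`.
#' @export
recmap <- function(chromosome, start, end, c_cM_Mb,
                   gamma_gc = 1.25e-7, L_gc = 518, sex_factor = 0.5) {
  n <- length(start)
  if (length(end) != n || length(c_cM_Mb) != n || n == 0L)
    stop("start, end and c_cM_Mb must have equal, positive length")
  o <- order(start)
  start <- start[o]; end <- end[o]; c_cM_Mb <- c_cM_Mb[o]
  if (any(end <= start)) stop("windows must have positive width")
  if (n > 1L && any(start[-1] < end[-n]))
    stop("recombination map windows overlap")
  if (n > 1L && any(start[-1] != end[-n]))
    stop("recombination map windows must be contiguous")
  if (any(c_cM_Mb < 0)) stop("crossover rates must be nonnegative")
  if (gamma_gc < 0) stop("gamma_gc must be nonnegative")
  if (L_gc <= 0) stop("L_gc must be positive")
  if (!sex_factor %in% c(0.5, 0.66))
    stop("sex_factor must be 0.5 (autosome) or 0.66 (X)")
  structure(list(chromosome = as.character(chromosome[1]),
                 start = as.numeric(start), end = as.numeric(end),
                 c_cM_Mb = as.numeric(c_cM_Mb),
                 gamma_gc = gamma_gc, L_gc = L_gc, sex_factor = sex_factor),
            class = "recmap")
}

#' @export
print.recmap <- function(x, ...) {
  cat(sprintf(
    "Recombination map: %s, %d windows [%g, %g) bp\n  c: median %.3g cM/Mb (range %.3g-%.3g); gamma_gc = %g, L_gc = %g bp; sex factor %g\n",
    x$chromosome, length(x$start), min(x$start), max(x$end),
    stats::median(x$c_cM_Mb), min(x$c_cM_Mb), max(x$c_cM_Mb),
    x$gamma_gc, x$L_gc, x$sex_factor))
  invisible(x)
}

#' Read a windowed crossover map from TSV
#'
#' Expects columns `chrom`, `start`, `end`, `c_cM_Mb` (header optional,
#' order fixed). Windows are sorted; gaps are filled with `c = 0` and
#' reported with a warning; overlaps are an error.
#'
#' @param path TSV file path.
#' @param ... passed to [recmap()] (`gamma_gc`, `L_gc`, `sex_factor`).
#' @return a [recmap()] object.
#' @export
read_recmap <- function(path, ...) {
  if (!file.exists(path)) stop("recombination map file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1]][2])
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("expected 4 columns: chrom, start, end, c_cM_Mb")
  names(d)[1:4] <- c("chrom", "start", "end", "c")
  d <- d[order(d$start), ]
  if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)]))
    stop("recombination map windows overlap in ", path)
  gaps <- which(d$start[-1] > d$end[-nrow(d)])
  if (length(gaps)) {
    warning(sprintf("%d gap(s) in recombination map filled with c = 0",
                    length(gaps)))
    fill <- data.frame(chrom = d$chrom[1], start = d$end[gaps],
                       end = d$start[gaps + 1], c = 0)
    d <- rbind(d[, c("chrom", "start", "end", "c")], fill)
    d <- d[order(d$start), ]
  }
  recmap(d$chrom[1], d$start, d$end, d$c, ...)
}

## Cumulative genetic position (Morgans per female meiosis) at arbitrary bp.
## c in cM/Mb = 1e-8 Morgans/bp.
recmap_genetic_pos <- function(map, pos) {
  if (any(pos < map$start[1] | pos > map$end[length(map$end)]))
    stop("position outside mapped extent")
  cum <- c(0, cumsum(map$c_cM_Mb * 1e-8 * (map$end - map$start)))
  i <- pmin(pmax(findInterval(pos, map$start), 1L), length(map$start))
  cum[i] + (pos - map$start[i]) * map$c_cM_Mb[i] * 1e-8
}

#' Genetic distance between two positions
#'
#' Piecewise-constant integration of the windowed crossover map, returned
#' in Morgans per female meiosis.
#'
#' @param map a [recmap()] object.
#' @param pos1,pos2 positions in bp within the mapped extent.
#' @return Morgans per female meiosis (vectorized; symmetric; 0 at equality).
#' @export
genetic_distance <- function(map, pos1, pos2) {
  abs(recmap_genetic_pos(map, pos2) - recmap_genetic_pos(map, pos1))
}

## Gene-conversion contribution to recombination between sites d bp apart:
## standard tract-overlap form, plateauing at gamma * L_gc for d >> L_gc.
gc_term <- function(d, gamma_gc, L_gc) {
  gamma_gc * L_gc * (1 - exp(-d / L_gc))
}

#' Pairwise recombination frequency between two sites
#'
#' Total recombination frequency per generation between two positions,
#' combining crossing over (from the windowed map) and, optionally, gene
#' conversion, then averaged over sexes via the map's `sex_factor`.
#' Frequencies below `1e-10` are set to 0 (fully linked) and capped at 1.
#' Positions falling in the same 1-kb window are treated as fully linked,
#' matching the windowed-landscape convention.
#'
#' @inheritParams genetic_distance
#' @param include_gc include the gene-conversion term (default `TRUE`).
#' @param window_bp width of the fully-linked window (default 1000; set to
#'   0 to disable the same-window rule).
#' @return recombination frequency in `[0, 1]` (vectorized).
#' @export
pairwise_r <- function(map, pos1, pos2, include_gc = TRUE, window_bp = 1000) {
  d_gen <- genetic_distance(map, pos1, pos2)
  d_phys <- abs(pos2 - pos1)
  r <- d_gen
  if (include_gc) r <- r + gc_term(d_phys, map$gamma_gc, map$L_gc)
  r <- map$sex_factor * r
  if (window_bp > 0) {
    same <- (pos1 %/% window_bp) == (pos2 %/% window_bp)
    r[same] <- 0
  }
  r[r < 1e-10] <- 0
  pmin(r, 1)
}

#' Trim low-recombination chromosome ends
#'
#' Removes sub-telomeric and sub-centromeric stretches: scanning inward
#' from each chromosome end, the kept region begins at the first run of at
#' least 3 consecutive windows with crossover rate > 1 cM/Mb.
#'
#' @param map a [recmap()] object (>= 3 windows).
#' @param min_c rate threshold in cM/Mb (default 1).
#' @param min_run required run length in windows (default 3).
#' @return list with `chromosome`, `keep_start`, `keep_end` (bp, on window
#'   boundaries).
#' @export
trim_chromosome <- function(map, min_c = 1, min_run = 3) {
  n <- length(map$start)
  if (n < min_run) stop("map must have at least ", min_run, " windows")
  ok <- map$c_cM_Mb > min_c
  run_start <- function(flags) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths >= min_run)[1]
    if (is.na(i)) return(NA_integer_)
    ends[i] - r$lengths[i] + 1L
  }
  lo <- run_start(ok)
  hi_rev <- run_start(rev(ok))
  if (is.na(lo) || is.na(hi_rev))
    stop("no run of ", min_run, " consecutive windows with c > ", min_c,
         " cM/Mb; whole arm is low-recombination")
  hi <- n - hi_rev + 1L
  if (lo > hi) stop("trim boundaries cross; arm effectively empty")
  list(chromosome = map$chromosome,
       keep_start = map$start[lo], keep_end = map$end[hi])
}

#' Write trimmed chromosome boundaries as BED
#'
#' @param trim result of [trim_chromosome()] (or a list of them).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_trim_bed <- function(trim, path) {
  if (!is.null(trim$chromosome)) trim <- list(trim)
  lines <- vapply(trim, function(t)
    sprintf("%s\t%d\t%d", t$chromosome, as.integer(t$keep_start),
            as.integer(t$keep_end)), character(1))
  writeLines(lines, path)
  invisible(path)
}
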