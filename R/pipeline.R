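#' Read a B track written by [write_b_track()]
#' @param path TSV/BedGraph path.
#' @return a `b_landscape` data.frame.
#' @export
read_b_track <- function(path) {
  header <- readLines(path, n = 1L)
  model_id <- sub(".*model_id=(\\S+).*", "\\1", header)
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("chromosome", "start", "end", "B"))
  d$E <- -log(d$B)
  attr(d, "model_id") <- model_id
  class(d) <- c("b_landscape", "data.frame")
  d
}

#' Write / read a segregating-site table
#' @param sites data.frame with `pos`, `n`, `derived`.
#' @param path TSV path.
#' @return `path` / the data.frame.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Published full-genome reference quantities
#'
#' Genome-wide values reported for the D. melanogaster analysis under the
#' default model; reproducing them requires the FlyBase r5.47 annotation,
#' the Comeron et al. (2012) recombination maps and the DPGP2 Rwanda (RG)
#' assemblies, hence `desk_scale = FALSE` throughout: they are recorded
#' for comparison, not recomputed by the test suite.
#'
#' @return data.frame with `id`, `description`, `value`, `units`,
#'   `model_id`, `desk_scale`.
#' @export
reference_targets <- function() {
  data.frame(
    id = c("median_B_genome", "median_B_trimmed", "frac_1kb_B_below_0.25",
           "xa_ratio_complete", "xa_ratio_trimmed", "median_B_gamma",
           "median_DB90_cM"),
    description = c(
      "genome-wide median B, default model",
      "median B across trimmed chromosome arms",
      "fraction of 1-kb windows with B < 0.25",
      "predicted X/A diversity ratio, complete chromosomes",
      "predicted X/A diversity ratio, trimmed chromosomes",
      "genome-wide median B under the gamma-DDFE model",
      "median genetic D_B90 across complete chromosomes"),
    value = c(0.591, 0.643, 0.19, 0.99, 0.92, 0.428, 5.5),
    units = c("B", "B", "fraction", "ratio", "ratio", "B", "cM"),
    model_id = c("M_LN,StdMut,CO+GC", "M_LN,StdMut,CO+GC",
                 "M_LN,StdMut,CO+GC", "M_LN,StdMut,CO+GC",
                 "M_LN,StdMut,CO+GC", "M_G,StdMut,CO+GC",
                 "M_LN,StdMut,CO+GC"),
    desk_scale = FALSE)
}

parse_cli_args <- function(args) {
  vals <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    vals[[key]] <- if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      i <- i + 1L; args[i]
    } else TRUE
    i <- i + 1L
  }
  vals
}

cli_get <- function(vals, key, default = NULL) {
  if (!is.null(vals[[key]])) vals[[key]]
  else if (!is.null(default)) default
  else stop("missing required option --", key)
}

#' Run a pipeline stage from command-line-style arguments
#'
#' Thin driver over the package functions, also usable from the installed
#' `cli/bgs.R` script. Subcommands: `simulate` (write a complete synthetic
#' fixture: annotation, TE track, recombination map, B track, site table,
#' gene table), `compute` (annotation + map -> B track), `diversity`
#' (site table + annotation -> window diversity TSV), `outliers` (B track
#' + diversity TSV -> outlier table TSV), `dbscale` (D_B quantiles for a
#' focal window), `protevo` (gene table + B track -> omega_R-B
#' correlation).
#'
#' @param subcommand one of the stages above.
#' @param args character vector of `--key value` options.
#' @return invisibly, the main object produced by the stage.
#' @export
run_pipeline <- function(subcommand, args = character()) {
  vals <- parse_cli_args(args)
  switch(subcommand,
    simulate = {
      outdir <- cli_get(vals, "outdir")
      spec <- synthetic_spec(
        seed = as.integer(cli_get(vals, "seed", "1")),
        chromosome_length = as.numeric(cli_get(vals, "length", "1e6")),
        n_genes = as.integer(cli_get(vals, "genes", "100")))
      gen <- generate_genome(spec, outdir)
      model <- parse_model_id(cli_get(vals, "model", "M_LN,StdMut,CO+GC"))
      cls <- classify_sites(gen$gff3, te_bed = gen$te_bed,
                            chrom_length = spec$chromosome_length)
      bl <- compute_B(count_selected_sites(cls), gen$recmap, model)
      write_b_track(bl, file.path(outdir, "b_track.tsv"))
      poly <- generate_polymorphism(bl, cls, spec)
      write_site_table(poly$sites, file.path(outdir, "sites.tsv"))
      write_gene_table(generate_gene_table(bl, spec),
                       file.path(outdir, "genes.tsv"))
      message("synthetic fixture written to ", outdir)
      invisible(gen)
    },
    compute = {
      model <- parse_model_id(cli_get(vals, "model", "M_LN,StdMut,CO+GC"))
      map <- read_recmap(cli_get(vals, "recmap"))
      cls <- classify_sites(cli_get(vals, "annotation"),
                            te_bed = vals[["tes"]],
                            chrom_length = max(map$end))
      bl <- compute_B(count_selected_sites(cls), map, model)
      write_b_track(bl, cli_get(vals, "out"))
      invisible(bl)
    },
    diversity = {
      len <- vals[["length"]]
      cls <- classify_sites(cli_get(vals, "annotation"),
                            te_bed = vals[["tes"]],
                            chrom_length = if (!is.null(len))
                              as.numeric(len) else NULL)
      sites <- read_site_table(cli_get(vals, "sites"))
      wd <- window_diversity(
        sites, cls,
        window_bp = as.numeric(cli_get(vals, "window", "1000")),
        n_total = as.integer(cli_get(vals, "haplotypes")))
      utils::write.table(wd, cli_get(vals, "out"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      invisible(wd)
    },
    outliers = {
      bl <- read_b_track(cli_get(vals, "b-track"))
      wd <- utils::read.table(cli_get(vals, "diversity"), sep = "\t",
                              header = TRUE)
      wb <- as.numeric(cli_get(vals, "window", "1000"))
      if (wb > bl$end[1] - bl$start[1]) bl <- aggregate_b(bl, wb)
      wd$B <- bl$B[match(wd$start, bl$start)]
      fit <- fit_baseline(wd[wd$included, ])
      tab <- studentized_residuals(
        fit, fdr_q = as.numeric(cli_get(vals, "fdr", "0.10")))
      utils::write.table(tab, cli_get(vals, "out"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      invisible(tab)
    },
    dbscale = {
      model <- parse_model_id(cli_get(vals, "model", "M_LN,StdMut,CO+GC"))
      cls <- classify_sites(cli_get(vals, "annotation"),
                            te_bed = vals[["tes"]])
      map <- read_recmap(cli_get(vals, "recmap"))
      db <- db_quantiles(count_selected_sites(cls), map, model,
                         focal_window = as.integer(cli_get(vals, "focal")))
      print(db)
      invisible(db)
    },
    protevo = {
      genes <- read_gene_table(cli_get(vals, "genes"))
      bl <- read_b_track(cli_get(vals, "b-track"))
      kept <- filter_genes(genes)$retained
      kept <- omega_residuals(kept)
      res <- correlate_b_omega(kept, bl)
      print(res)
      invisible(res)
    },
    stop("unknown subcommand '", subcommand,
         "'; expected simulate|compute|diversity|outliers|dbscale|protevo"))
}
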