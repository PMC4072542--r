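#' Parse a BGS model identifier into a fully-resolved configuration
#'
#' Model identifiers follow the grammar `M_{DDFE},{Mut},{Rec}` with DDFE in
#' `LN` (log-normal), `G` (gamma), or the two-DDFE hybrids `LN/G` and
#' `G/LN` (coding/noncoding); Mut in `StdMut` (U = 1.2, u = 8.4e-9) or
#' `LowMut` (U = 0.6, u = 4.2e-9); Rec in `CO+GC` or `CO` (crossover only).
#' The default model of the analysis is `M_LN,StdMut,CO+GC`.
#'
#' @param model_id model string, e.g. `"M_LN,StdMut,CO+GC"`.
#' @param chromosome `"autosome"` or `"X"`; selects the selection-coefficient
#'   scaling (`s_X = 2/3 s_A`) and the truncation threshold.
#' @param Ne effective population size (default 1e6).
#' @param config a [site_class_config()].
#' @param gamma_gc,L_gc gene-conversion parameters.
#' @return list of class `"bgs_model"` with resolved DDFE specs per site
#'   class, mutation rates, threshold and recombination settings.
#' @export
parse_model_id <- function(model_id = "M_LN,StdMut,CO+GC",
                           chromosome = c("autosome", "X"), Ne = 1e6,
                           config = site_class_config(),
                           gamma_gc = 1.25e-7, L_gc = 518) {
  chromosome <- match.arg(chromosome)
  valid_ddfe <- c("LN", "G", "LN/G", "G/LN")
  valid_mut <- c("StdMut", "LowMut")
  valid_rec <- c("CO+GC", "CO")
  usage <- function() stop(
    "unknown model id '", model_id, "'; expected M_{",
    paste(valid_ddfe, collapse = "|"), "},{",
    paste(valid_mut, collapse = "|"), "},{",
    paste(valid_rec, collapse = "|"), "}", call. = FALSE)
  if (!grepl("^M_", model_id)) usage()
  parts <- strsplit(sub("^M_", "", model_id), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L) usage()
  if (!parts[1] %in% valid_ddfe || !parts[2] %in% valid_mut ||
      !parts[3] %in% valid_rec) usage()

  scale <- if (chromosome == "X") 2 / 3 else 1
  mk <- function(fam) switch(fam,
    LN = ddfe("lognormal", median_s = 2.31e-4, sd_log = 5.308,
              dominance_h = 0.5, chromosome_scale = scale),
    G  = ddfe("gamma", shape_k = 0.3, mean_s = 2.5e-3,
              dominance_h = 0.5, chromosome_scale = scale))
  fams <- strsplit(parts[1], "/", fixed = TRUE)[[1]]
  ddfe_coding <- mk(fams[1])
  ddfe_noncoding <- mk(fams[length(fams)])

  U <- if (parts[2] == "StdMut") 1.2 else 0.6
  u <- if (parts[2] == "StdMut") 8.4e-9 else 4.2e-9

  structure(list(
    model_id = model_id, chromosome = chromosome,
    ddfe_coding = ddfe_coding, ddfe_noncoding = ddfe_noncoding,
    hybrid = length(fams) > 1L,
    U = U, u = u, include_gc = parts[3] == "CO+GC",
    Ne = Ne, threshold = neutral_threshold(Ne, chromosome),
    config = config, gamma_gc = gamma_gc, L_gc = L_gc,
    sex_factor = if (chromosome == "X") 0.66 else 0.5),
    class = "bgs_model")
}

#' @export
print.bgs_model <- function(x, ...) {
  cat(sprintf(
    "BGS model %s (%s): U = %g (u = %g/bp), %s, Ne = %g, s_T = %g\n",
    x$model_id, x$chromosome, x$U, x$u,
    if (x$include_gc) "crossover + gene conversion" else "crossover only",
    x$Ne, x$threshold$s_T))
  cat(sprintf("  coding DDFE: %s; noncoding DDFE: %s\n",
              x$ddfe_coding$family, x$ddfe_noncoding$family))
  invisible(x)
}

#' All eight single-DDFE model identifiers
#' @return character vector of the 2 x 2 x 2 model grid.
#' @export
model_grid <- function() {
  as.vector(outer(outer(c("M_LN", "M_G"), c("StdMut", "LowMut"),
                        paste, sep = ","),
                  c("CO+GC", "CO"), paste, sep = ","))
}
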