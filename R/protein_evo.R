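#' Filter a per-gene molecular-evolution table
#'
#' Applies the gene-inclusion rules for efficacy-of-selection analyses:
#' drop genes with short coding sequences (`< 450` bp), sparse alignments
#' (`< 100` amino acids present in all species), premature stop codons,
#' evidence of positive selection (BH q of the M1a-vs-M2a test `< 0.05`),
#' or `omega > 0.75` (suspected positive selection or pseudogenization).
#' The retained set is the intersection of the rules; removal counts are
#' audited per rule in application order.
#'
#' @param records data.frame with columns `gene_id`, `cds_length_bp`,
#'   `aligned_aa`, `dN`, `dS`, `omega`, `premature_stop`,
#'   `positive_selection_q` (and typically `chromosome`, `midpoint`).
#' @param min_cds minimum CDS length in bp (450).
#' @param min_aa minimum aligned amino acids (100).
#' @param max_omega maximum omega (0.75).
#' @param pos_sel_q positive-selection q threshold (0.05).
#' @return list with `retained` (data.frame) and `removed` (named counts
#'   per rule, in application order).
#' @export
filter_genes <- function(records, min_cds = 450, min_aa = 100,
                         max_omega = 0.75, pos_sel_q = 0.05) {
  need <- c("gene_id", "cds_length_bp", "aligned_aa", "dN", "dS", "omega",
            "premature_stop", "positive_selection_q")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  keep <- rep(TRUE, nrow(records))
  removed <- integer(0)
  apply_rule <- function(drop, name) {
    removed[[name]] <<- sum(keep & drop)
    keep <<- keep & !drop
  }
  apply_rule(records$cds_length_bp < min_cds, "short_cds")
  apply_rule(records$aligned_aa < min_aa, "sparse_alignment")
  apply_rule(records$premature_stop, "premature_stop")
  apply_rule(records$positive_selection_q < pos_sel_q, "positive_selection")
  apply_rule(records$omega > max_omega, "high_omega")
  list(retained = records[keep, , drop = FALSE], removed = removed)
}

#' Efficacy-of-selection residuals: omega controlling for dS
#'
#' Least-squares residuals of `omega` on `dS` (`omega_R`), fitted
#' separately for autosomes and the X chromosome. `dS` absorbs both weak
#' selection on synonymous sites and variation in coalescent depth, so
#' `omega_R` isolates variation in the efficacy of selection on
#' amino-acid changes.
#'
#' @param records filtered gene table; needs `omega`, `dS`, and optionally
#'   `group` (`"autosome"`/`"X"`, default all autosome).
#' @return `records` with an added `omega_R` column.
#' @export
omega_residuals <- function(records) {
  if (is.null(records$group)) records$group <- "autosome"
  records$omega_R <- NA_real_
  for (g in unique(records$group)) {
    i <- which(records$group == g)
    if (length(i) < 10) stop("need at least 10 genes per group")
    if (stats::sd(records$dS[i]) == 0)
      stop("dS constant within group '", g, "'; residual fit degenerate")
    fit <- stats::lm(omega ~ dS, data = records[i, ])
    records$omega_R[i] <- stats::residuals(fit)
  }
  records
}

#' Correlate efficacy-of-selection residuals with B
#'
#' Spearman rank correlation between `omega_R` and the local strength of
#' background selection, either with per-gene B looked up at the CDS
#' midpoint or after averaging `omega_R` within 100-kb windows. A negative
#' correlation indicates reduced efficacy of purifying selection where
#' BGS is strong (low B), the Hill-Robertson expectation.
#'
#' @param records gene table with `omega_R`, `chromosome`, `midpoint`, and
#'   optionally `group`.
#' @param landscape a `b_landscape` for the genes' chromosome (1-kb or
#'   coarser windows).
#' @param aggregation `"gene"` (midpoint lookup) or `"100kb"` (mean
#'   `omega_R` vs mean B per 100-kb window).
#' @return list per group (`all` plus each `group` level) of
#'   `list(rho, p_value, n)`; genes falling outside the landscape are
#'   dropped with a warning.
#' @export
correlate_b_omega <- function(records, landscape,
                              aggregation = c("gene", "100kb")) {
  aggregation <- match.arg(aggregation)
  if (is.null(records$group)) records$group <- "autosome"
  idx <- findInterval(records$midpoint, landscape$start)
  ok <- idx >= 1 & records$midpoint <= max(landscape$end) &
    records$chromosome == landscape$chromosome[1]
  if (any(!ok))
    warning(sum(!ok), " gene(s) fall outside the B landscape; excluded")
  rec <- records[ok, , drop = FALSE]
  rec$B <- landscape$B[idx[ok]]

  cor_of <- function(x, y) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
  }
  one_group <- function(d) {
    if (aggregation == "gene") return(cor_of(d$B, d$omega_R))
    w <- d$midpoint %/% 1e5
    bw <- tapply(d$B, w, mean)
    ow <- tapply(d$omega_R, w, mean)
    cor_of(as.vector(bw), as.vector(ow))
  }
  out <- list(all = one_group(rec))
  for (g in unique(rec$group))
    out[[g]] <- one_group(rec[rec$group == g, , drop = FALSE])
  out
}

#' Read / write per-gene molecular-evolution tables
#'
#' TSV with the columns documented in [filter_genes()].
#'
#' @param path file path.
#' @return data.frame (`read_gene_table`) or `path` (`write_gene_table`).
#' @export
read_gene_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if ("premature_stop" %in% names(d))
    d$premature_stop <- as.logical(d$premature_stop)
  d
}

#' @param records gene table to write.
#' @rdname read_gene_table
#' @export
write_gene_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
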