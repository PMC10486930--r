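# Single-cell qPCR workflow: control-gene QC, delta-Ct expression,
# whole-population comparison, pooled z-normalization, and per-gene
# confidence-interval reactivity calls.

#' Quality-filter cells on control-gene detection
#'
#' A cell is removed iff its control genes (Gapdh, Oaz1) exceed the Ct
#' cutoff. The default mode `"both"` removes a cell only when *both*
#' controls are undetected (the literal reading of the QC rule); `"either"`
#' removes a cell when any control fails.
#'
#' @param x a [ct_table()].
#' @param cutoff Ct cutoff: undetected means Ct > cutoff (default 32).
#' @param mode `"both"` (default) or `"either"`.
#' @return the filtered [ct_table()] with attribute `removed` (cell ids).
#' @export
qc_filter <- function(x, cutoff = 32, mode = c("both", "either")) {
  stopifnot(inherits(x, "ct_table"))
  mode <- match.arg(mode)
  fails <- x$ct[, x$control_genes, drop = FALSE] > cutoff
  drop <- if (mode == "both") apply(fails, 1, all) else apply(fails, 1, any)
  out <- x
  out$ct <- x$ct[!drop, , drop = FALSE]
  out$group <- droplevels(x$group[!drop])
  attr(out, "removed") <- rownames(x$ct)[drop]
  out
}

#' Delta-Ct and expression matrices
#'
#' Per cell and gene: `dct = Ct_gene - Ct_reference` and
#' `expression = 2^(-dct)`. Cells whose reference gene sits at the censoring
#' ceiling (undetected) have all values set to `NA` (flagged missing).
#' Targets censored at the ceiling keep their near-zero finite expression
#' `2^-(ceiling - Ct_ref)` so cells stay comparable without dropping rows.
#'
#' @param x a [ct_table()] (QC already applied).
#' @return list with matrices `dct` and `expression` (cells x target genes;
#'   control genes excluded) plus `group`.
#' @export
delta_ct <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  ref <- x$ct[, x$reference_gene]
  targets <- setdiff(colnames(x$ct), x$control_genes)
  dct <- x$ct[, targets, drop = FALSE] - ref
  dct[ref >= x$ceiling, ] <- NA_real_
  list(dct = dct, expression = 2^(-dct), group = x$group)
}

#' Whole-population expression comparison
#'
#' Per gene: fold change = mean(expression treated) / mean(expression
#' control), a two-sided two-sample t-test on expression values, and a
#' Bonferroni-corrected p over the gene panel. The fold change deliberately
#' uses the ratio of group mean expressions rather than `2^-ddCt` of mean
#' delta-Ct: the two differ when expression is driven by a reactive
#' subpopulation, and the mean-expression form reflects the population
#' average actually measured.
#'
#' @param expr cells x genes expression matrix (from [delta_ct()]).
#' @param group per-cell labels (2 levels).
#' @param treated level regarded as treated (default: second level).
#' @param n_genes_for_correction Bonferroni denominator (default:
#'   number of genes in `expr`).
#' @param var_equal pooled-variance t (default TRUE, mirroring classic
#'   `ttest2`); FALSE gives Welch.
#' @return data.frame: `gene`, `fold_change`, `p_raw`, `p_bonf`,
#'   `mean_treated`, `mean_control`, `n_treated`, `n_control`.
#' @export
population_comparison <- function(expr, group, treated = NULL,
                                  n_genes_for_correction = ncol(expr),
                                  var_equal = TRUE) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L, nrow(expr) == length(group))
  treated <- treated %||% levels(group)[2]
  control <- setdiff(levels(group), treated)
  out <- lapply(colnames(expr), function(g) {
    et <- expr[group == treated, g]; ec <- expr[group == control, g]
    et <- et[!is.na(et)]; ec <- ec[!is.na(ec)]
    if (length(et) < 2 || length(ec) < 2)
      return(data.frame(gene = g, fold_change = NA_real_, p_raw = NA_real_,
                        p_bonf = NA_real_, mean_treated = NA_real_,
                        mean_control = NA_real_, n_treated = length(et),
                        n_control = length(ec)))
    mt <- mean(et); mc <- mean(ec)
    fc <- if (mc > 0) mt / mc else NA_real_   # zero control mean: undefined
    p <- if (sd(et) == 0 && sd(ec) == 0) {
      if (mt == mc) 1 else 0
    } else t.test(et, ec, var.equal = var_equal)$p.value
    data.frame(gene = g, fold_change = fc, p_raw = p,
               p_bonf = min(1, p * n_genes_for_correction),
               mean_treated = mt, mean_control = mc,
               n_treated = length(et), n_control = length(ec))
  })
  do.call(rbind, out)
}

#' Pooled z-normalization of delta-Ct values
#'
#' Per gene, delta-Ct values are averaged over *all* cells of the comparison
#' (both groups pooled); each cell's value is subtracted from that average
#' and divided by the pooled (sample) standard deviation:
#' `z = (mean_pooled - dct) / sd_pooled`. The sign convention makes higher
#' expression (lower delta-Ct) positive. Genes with zero pooled sd (or < 2
#' usable cells) are marked non-informative and their z set to missing.
#'
#' `reference = "control"` normalizes against the control group's mean and sd
#' instead; this departs from the pooled formula but makes the downstream
#' confidence-interval call a calibrated test of the treated group against
#' the control distribution (see the methods vignette).
#'
#' @param dct cells x genes delta-Ct matrix.
#' @param group per-cell labels (used only for `reference = "control"`).
#' @param reference `"pooled"` (default) or `"control"`.
#' @param control control-group level (default: first level of `group`).
#' @return list with `z` (cells x genes) and `non_informative`
#'   (logical per gene).
#' @export
normalize_pooled_z <- function(dct, group = NULL,
                               reference = c("pooled", "control"),
                               control = NULL) {
  reference <- match.arg(reference)
  z <- dct; z[] <- NA_real_
  ni <- setNames(logical(ncol(dct)), colnames(dct))
  if (reference == "control") {
    stopifnot(!is.null(group))
    group <- factor(group)
    control <- control %||% levels(group)[1]
    sel <- group == control
  } else sel <- rep(TRUE, nrow(dct))
  for (g in colnames(dct)) {
    v <- dct[sel, g]; v <- v[!is.na(v)]
    if (length(v) < 2 || sd(v) == 0) { ni[g] <- TRUE; next }
    z[, g] <- (mean(v) - dct[, g]) / sd(v)
  }
  list(z = z, non_informative = ni)
}

#' Per-gene reactivity calls from confidence intervals
#'
#' For each gene, computes the mean z-score of treated cells with a Student-t
#' 95 percent confidence interval, `mean(z) +/- t(0.975, n-1) * sd(z)/sqrt(n)`.
#' A gene is called `up` when the interval lies entirely above 0, `down` when
#' entirely below, `ns` otherwise, `non_informative` when no interval can be
#' formed (fewer than 2 usable treated cells or a degenerate gene).
#'
#' @param z cells x genes z matrix (from [normalize_pooled_z()]).
#' @param group per-cell labels.
#' @param treated treated level (default: second level).
#' @param conf confidence level (default 0.95).
#' @param non_informative optional logical per gene (degenerate genes).
#' @return data.frame of gene calls: `gene`, `z_mean_treated`, `ci_lo`,
#'   `ci_hi`, `n_treated`, `call`.
#' @export
ci_call <- function(z, group, treated = NULL, conf = 0.95,
                    non_informative = NULL) {
  group <- factor(group)
  treated <- treated %||% levels(group)[nlevels(group)]
  alpha <- 1 - conf
  out <- lapply(colnames(z), function(g) {
    if (!is.null(non_informative) && isTRUE(non_informative[[g]]))
      return(data.frame(gene = g, z_mean_treated = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_treated = 0L,
                        call = "non_informative"))
    zt <- z[group == treated, g]; zt <- zt[!is.na(zt)]
    n <- length(zt)
    if (n < 2)
      return(data.frame(gene = g, z_mean_treated = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_treated = n,
                        call = "non_informative"))
    m <- mean(zt)
    half <- qt(1 - alpha / 2, n - 1) * sd(zt) / sqrt(n)
    lo <- m - half; hi <- m + half
    call <- if (lo > 0) "up" else if (hi < 0) "down" else "ns"
    data.frame(gene = g, z_mean_treated = m, ci_lo = lo, ci_hi = hi,
               n_treated = n, call = call)
  })
  do.call(rbind, out)
}

#' Export the heatmap matrix (genes x cells z values) as CSV
#'
#' Writes the normalized z matrix in heatmap orientation — rows are genes,
#' columns are individual cells (grouped by cohort, in table order) — for
#' plotting.
#'
#' @param x a [ct_table()].
#' @param path output CSV.
#' @param qc_cutoff,reference as in [gene_calls()].
#' @return the path, invisibly.
#' @export
write_heatmap_csv <- function(x, path, qc_cutoff = 32, reference = "pooled") {
  xq <- qc_filter(x, cutoff = qc_cutoff)
  dd <- delta_ct(xq)
  nz <- normalize_pooled_z(dd$dct, dd$group, reference = reference)
  z <- t(nz$z[order(dd$group), , drop = FALSE])
  colnames(z) <- rownames(xq$ct)[order(dd$group)]
  df <- data.frame(gene = rownames(z), z, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Full per-gene call table for a Ct table
#'
#' Convenience wrapper chaining [qc_filter()], [delta_ct()],
#' [population_comparison()], [normalize_pooled_z()] and [ci_call()] into the
#' per-gene summary used by the pipeline report.
#'
#' @param x a [ct_table()].
#' @param qc_cutoff control-gene Ct cutoff (default 32).
#' @param treated treated level (default: second group level).
#' @param reference normalization reference, see [normalize_pooled_z()].
#' @param n_genes_for_correction Bonferroni denominator (default panel size).
#' @return data.frame (`gene_calls`): fold change, raw and Bonferroni p,
#'   treated z mean, CI bounds and call per gene.
#' @export
gene_calls <- function(x, qc_cutoff = 32, treated = NULL,
                       reference = "pooled",
                       n_genes_for_correction = NULL) {
  xq <- qc_filter(x, cutoff = qc_cutoff)
  dd <- delta_ct(xq)
  n_genes <- n_genes_for_correction %||% ncol(dd$expression)
  pc <- population_comparison(dd$expression, dd$group,
                              treated = treated,
                              n_genes_for_correction = n_genes)
  nz <- normalize_pooled_z(dd$dct, dd$group, reference = reference)
  cc <- ci_call(nz$z, dd$group, treated = treated,
                non_informative = nz$non_informative)
  names(cc)[names(cc) == "n_treated"] <- "n_treated_z"
  merge(pc, cc, by = "gene", sort = FALSE)
}
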