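# Synthetic single-cell Ct tables with a reactive-subpopulation mixture.
#
# Model: per cell, the reference gene (Gapdh) cycles to Ct ~ N(20, 0.8) and
# the second control (Oaz1) ~ N(24, 0.8). Target genes have
# delta-Ct ~ N(baseline_dct_mean, baseline_dct_sd) relative to Gapdh.
# In the treated group a Bernoulli(reactive_fraction) flag marks each cell
# reactive; reactive cells have their delta-Ct shifted by -log2(fold_change)
# for every spiked gene (the same cells are reactive across genes, which is
# what produces the "subset of highly active cells" heatmap structure rather
# than a whole-population shift). Dropout replaces a measurement with the
# censoring ceiling (undetected = Ct 40, a common qPCR convention).
#
# The default baseline_dct_sd of 0.85 Ct is back-derived from the study
# design this emulates: n = 12 cells per condition detecting a 2-fold change
# at alpha = 0.05 with power 0.8 implies a per-cell delta-Ct sd of ~0.85.

#' Default single-cell qPCR gene panel
#'
#' 19 genes: 8 phagocytosis/engulfment markers, 2 mitophagy markers,
#' 4 A1 (neurotoxic) and 5 A2 (neuroprotective) reactivity markers.
#'
#' @return named character vector of gene class by gene.
#' @export
default_gene_panel <- function() {
  c(Abca1 = "phagocytosis", Abca7 = "phagocytosis", Dock1 = "phagocytosis",
    Gulp1 = "phagocytosis", Lamp1 = "phagocytosis", Lgals3 = "phagocytosis",
    Megf10 = "phagocytosis", Mfge8 = "phagocytosis",
    Pink1 = "mitophagy", Park2 = "mitophagy",
    Fbln5 = "A1", `H2-T23` = "A1", Psmb8 = "A1", Srgn = "A1",
    Clcf1 = "A2", Emp1 = "A2", Ptx3 = "A2", Stat3 = "A2", Tgm1 = "A2")
}

#' Single-cell Ct table container
#'
#' @param ct cells x genes numeric matrix of Ct values (rownames = cell ids).
#' @param group per-cell group labels.
#' @param control_genes internal control genes (default Gapdh, Oaz1).
#' @param reference_gene reference for delta-Ct (must be a control gene).
#' @param ceiling censoring ceiling for undetected reactions (default 40).
#' @return object of class `ct_table`.
#' @export
ct_table <- function(ct, group, control_genes = c("Gapdh", "Oaz1"),
                     reference_gene = "Gapdh", ceiling = 40) {
  ct <- as.matrix(ct)
  stopifnot(length(group) == nrow(ct), all(control_genes %in% colnames(ct)),
            reference_gene %in% control_genes)
  if (any(ct <= 0 | ct > ceiling, na.rm = TRUE))
    stop_gq("Ct values must lie in (0, ceiling]")
  # group levels follow order of appearance (control listed first by
  # convention); downstream the treated group defaults to the second level
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  structure(list(ct = ct, group = factor(group), control_genes = control_genes,
                 reference_gene = reference_gene, ceiling = ceiling),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d cells x %d genes (%s)\n", nrow(x$ct), ncol(x$ct),
              paste(sprintf("%s n=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic single-cell Ct table with known mixture truth
#'
#' @param n_control,n_treated cells per group (each >= 2).
#' @param genes target gene names (default: names of [default_gene_panel()]).
#' @param reactive_fraction proportion of treated cells that are reactive.
#' @param fold_change expression fold change in reactive cells: a scalar
#'   applied to all genes or a named vector (genes absent from the vector get
#'   fold 1). `NULL` means no spike (pure null).
#' @param baseline_dct_mean,baseline_dct_sd delta-Ct baseline (Ct units).
#' @param dropout_prob probability a target measurement is censored at the
#'   ceiling; `control_dropout` likewise for control genes.
#' @param ceiling censoring ceiling (Ct 40).
#' @param group_labels labels for (control, treated).
#' @param seed RNG seed (required).
#' @return list with `table` (a [ct_table()]) and `truth` (class `ct_truth`:
#'   the parameters plus `reactive` — per-cell logical flags, control cells
#'   all FALSE).
#' @examples
#' sim <- make_ct_table(n_control = 5, n_treated = 5,
#'                      fold_change = c(Gulp1 = 8), seed = 1)
#' sim$table
#' @export
make_ct_table <- function(n_control = 33, n_treated = 39,
                          genes = names(default_gene_panel()),
                          reactive_fraction = 0.3, fold_change = NULL,
                          baseline_dct_mean = 5, baseline_dct_sd = 0.85,
                          dropout_prob = 0.05, control_dropout = 0.02,
                          ceiling = 40,
                          group_labels = c("saline", "microbead"), seed) {
  stopifnot(n_control >= 2, n_treated >= 2, reactive_fraction >= 0,
            reactive_fraction <= 1, baseline_dct_sd >= 0)
  if (length(genes) == 0L) stop_gq("gene list must not be empty")
  if (missing(seed)) stop_gq("make_ct_table() requires an explicit seed")
  fc <- setNames(rep(1, length(genes)), genes)
  if (!is.null(fold_change)) {
    if (is.null(names(fold_change)) && length(fold_change) == 1L) {
      fc[] <- fold_change
    } else {
      stopifnot(all(names(fold_change) %in% genes))
      fc[names(fold_change)] <- fold_change
    }
  }
  if (any(fc <= 0)) stop_gq("fold_change must be positive")
  with_seed(seed, {
    n <- n_control + n_treated
    group <- factor(rep(group_labels, c(n_control, n_treated)),
                    levels = group_labels)   # control first, treated second
    reactive <- c(rep(FALSE, n_control),
                  as.logical(rbinom(n_treated, 1, reactive_fraction)))
    gapdh <- rnorm(n, 20, 0.8)
    oaz1 <- rnorm(n, 24, 0.8)
    dct <- matrix(rnorm(n * length(genes), baseline_dct_mean, baseline_dct_sd),
                  n, length(genes), dimnames = list(NULL, genes))
    shift <- outer(reactive, log2(fc))     # reactive cells express fc-fold more
    dct <- dct - shift
    ct <- dct + gapdh
    drop <- matrix(runif(n * length(genes)) < dropout_prob, n, length(genes))
    ct[drop] <- ceiling
    ct[ct > ceiling] <- ceiling
    ct[ct <= 0] <- 0.1
    gapdh[runif(n) < control_dropout] <- ceiling
    oaz1[runif(n) < control_dropout] <- ceiling
    m <- cbind(Gapdh = pmin(gapdh, ceiling), Oaz1 = pmin(oaz1, ceiling), ct)
    rownames(m) <- sprintf("cell_%03d", seq_len(n))
    tab <- ct_table(m, group, ceiling = ceiling)
    truth <- structure(list(reactive_fraction = reactive_fraction,
                            fold_change_per_gene = fc,
                            baseline_dct_mean = baseline_dct_mean,
                            baseline_dct_sd = baseline_dct_sd,
                            dropout_prob = dropout_prob, reactive = reactive,
                            group = tab$group),
                       class = "ct_truth")
    list(table = tab, truth = truth)
  })
}

#' Read / write Ct tables as CSV
#'
#' Format: header `cell_id,group,<gene>,...`; blank cells mean undetected and
#' are read back as the censoring ceiling.
#'
#' @param x a [ct_table()].
#' @param path CSV file path.
#' @param ... passed to [ct_table()] (e.g. `control_genes`, `ceiling`).
#' @return `write_ct_csv()`: path, invisibly; `read_ct_csv()`: a [ct_table()].
#' @export
write_ct_csv <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  df <- data.frame(cell_id = rownames(x$ct), group = as.character(x$group),
                   x$ct, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path, ...) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("cell_id", "group") %in% names(df)))
  m <- as.matrix(df[, setdiff(names(df), c("cell_id", "group")), drop = FALSE])
  rownames(m) <- df$cell_id
  args <- list(...)
  ceiling <- args$ceiling %||% 40
  m[is.na(m)] <- ceiling
  do.call(ct_table, c(list(ct = m, group = df$group), args))
}
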