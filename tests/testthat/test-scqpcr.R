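make_tiny_table <- function(ct_rows, groups, genes = c("GeneA", "GeneB")) {
  m <- do.call(rbind, ct_rows)
  colnames(m) <- c("Gapdh", "Oaz1", genes)[seq_len(ncol(m))]
  rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  ct_table(m, groups)
}

test_that("qc_filter removes cells only when both controls fail (default)", {
  tab <- make_tiny_table(list(c(35, 33, 25, 25),     # both fail -> removed
                              c(25, 35, 25, 25),     # one fails -> retained
                              c(20, 22, 25, 25)),    # both pass -> retained
                         groups = c("a", "a", "b"))
  out <- qc_filter(tab)
  expect_identical(rownames(out$ct), c("c02", "c03"))
  expect_identical(attr(out, "removed"), "c01")
  out2 <- qc_filter(tab, mode = "either")
  expect_identical(rownames(out2$ct), "c03")
  # boundary: Ct exactly at the cutoff passes
  tab3 <- make_tiny_table(list(c(32, 32, 25, 25)), groups = "a")
  expect_identical(nrow(qc_filter(tab3)$ct), 1L)
})

test_that("delta_ct computes 2^-dCt and flags reference dropouts", {
  tab <- make_tiny_table(list(c(20, 24, 25, 20),
                              c(20, 24, 19, 20),
                              c(40, 24, 25, 25)),    # reference undetected
                         groups = c("a", "a", "b"))
  dd <- delta_ct(tab)
  expect_equal(dd$dct[1, "GeneA"], 5)
  expect_equal(dd$expression[1, "GeneA"], 0.03125)
  expect_equal(dd$expression[1, "GeneB"], 1)         # Ct_target = Ct_ref
  expect_equal(dd$dct[2, "GeneA"], -1)
  expect_equal(dd$expression[2, "GeneA"], 2)
  expect_true(all(is.na(dd$dct[3, ])))
  # control genes are not part of the target matrices
  expect_false(any(c("Gapdh", "Oaz1") %in% colnames(dd$dct)))
})

test_that("population comparison reports mean-ratio fold changes and Bonferroni p", {
  expr <- cbind(g1 = c(0.02, 0.02, 0.02, 0.05, 0.05, 0.05),
                g2 = c(1, 2, 3, 1, 2, 3))
  grp <- factor(rep(c("ctl", "trt"), each = 3), levels = c("ctl", "trt"))
  pc <- population_comparison(expr, grp, n_genes_for_correction = 19)
  expect_equal(pc$fold_change[pc$gene == "g1"], 2.5)
  expect_equal(pc$fold_change[pc$gene == "g2"], 1)
  expect_equal(pc$p_raw[pc$gene == "g2"], 1)
  expect_equal(pc$p_bonf, pmin(1, pc$p_raw * 19))
  # degenerate control mean
  expr0 <- cbind(g1 = c(0, 0, 0, 1, 1, 2))
  expect_true(is.na(population_comparison(expr0, grp)$fold_change))
})

test_that("fold-change estimates recover the population mixture truth", {
  # reactive_fraction 0.4 at 8-fold means a population-mean ratio of
  # 1 + 0.4 * (8 - 1) = 3.8; the median estimate over seeds should sit
  # within 25% of that
  folds <- vapply(1:200, function(s) {
    sim <- make_ct_table(n_control = 30, n_treated = 30,
                         reactive_fraction = 0.4, fold_change = 8,
                         dropout_prob = 0, seed = s)
    dd <- delta_ct(qc_filter(sim$table))
    pc <- population_comparison(dd$expression, dd$group)
    mean(pc$fold_change)
  }, numeric(1))
  expect_lt(abs(median(folds) - 3.8) / 3.8, 0.25)
})

test_that("pooled z-normalization centers and scales per gene", {
  dct <- cbind(g1 = c(4, 6), g2 = c(1, 3))
  nz <- normalize_pooled_z(dct)
  expect_equal(nz$z[, "g1"], c(1, -1) / sqrt(2), tolerance = 1e-12)
  # sign convention: the low-dCt (high expression) cell gets positive z
  expect_gt(nz$z[1, "g1"], 0)
  set.seed(7)
  big <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("g", 1:6)))
  nzb <- normalize_pooled_z(big)
  expect_equal(unname(colMeans(nzb$z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(nzb$z, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # constant gene is non-informative
  const <- cbind(g1 = rep(2, 5), g2 = rnorm(5))
  nzc <- normalize_pooled_z(const)
  expect_true(nzc$non_informative[["g1"]])
  expect_true(all(is.na(nzc$z[, "g1"])))
})

test_that("control-referenced normalization uses only control moments", {
  dct <- cbind(g = c(1, 3, 10, 12))
  grp <- factor(c("ctl", "ctl", "trt", "trt"), levels = c("ctl", "trt"))
  nz <- normalize_pooled_z(dct, grp, reference = "control")
  expect_equal(unname(nz$z[1:2, "g"]), c(1, -1) / sqrt(2))
  expect_equal(unname(nz$z[3, "g"]), (2 - 10) / sqrt(2))
})

test_that("ci_call applies the t-interval call rule", {
  z <- cbind(up = c(NA, NA, 1.0, 1.1, 0.9, 1.0),
             flat = c(NA, NA, -1, 1, -0.5, 0.5))
  grp <- factor(rep(c("ctl", "trt"), c(2, 4)), levels = c("ctl", "trt"))
  calls <- ci_call(z, grp)
  up <- calls[calls$gene == "up", ]
  # hand-computed interval: mean 1, sd 0.08165, half-width 0.1299
  expect_equal(up$z_mean_treated, 1)
  expect_equal(up$ci_lo, 1 - qt(0.975, 3) * sd(c(1, 1.1, 0.9, 1)) / 2,
               tolerance = 1e-12)
  expect_identical(up$call, "up")
  expect_identical(calls$call[calls$gene == "flat"], "ns")
  # a gene with < 2 treated values gets no call
  z2 <- cbind(g = c(1, 2, 3, NA, NA, NA))
  expect_identical(ci_call(z2, grp)$call, "non_informative")
  # down-regulation is symmetric
  z3 <- cbind(g = c(NA, NA, -1, -1.1, -0.9, -1))
  expect_identical(ci_call(z3, grp)$call, "down")
})

test_that("fold changes are invariant to relabeling cells within a group", {
  sim <- make_ct_table(n_control = 12, n_treated = 12, fold_change = 4, seed = 5)
  dd <- delta_ct(qc_filter(sim$table))
  pc1 <- population_comparison(dd$expression, dd$group)
  perm <- c(sample(which(dd$group == "saline")), sample(which(dd$group == "microbead")))
  pc2 <- population_comparison(dd$expression[perm, ], dd$group[perm])
  expect_equal(pc1$fold_change, pc2$fold_change)
  expect_equal(pc1$p_raw, pc2$p_raw)
})

test_that("the heatmap export is genes x cells in group order", {
  sim <- make_ct_table(n_control = 5, n_treated = 6, dropout_prob = 0,
                       control_dropout = 0, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_csv(sim$table, path)
  hm <- read.csv(path, check.names = FALSE)
  expect_identical(hm$gene, names(default_gene_panel()))
  expect_identical(ncol(hm), 12L)            # gene column + 11 cells
  # pooled z: each gene row averages to zero over all cells
  expect_equal(unname(rowMeans(hm[, -1])), rep(0, nrow(hm)), tolerance = 1e-12)
})

test_that("gene_calls chains the workflow end to end", {
  sim <- make_ct_table(n_control = 20, n_treated = 20,
                       reactive_fraction = 1, fold_change = c(Gulp1 = 8),
                       baseline_dct_sd = 0.3, dropout_prob = 0, seed = 8)
  gc <- gene_calls(sim$table)
  expect_setequal(names(default_gene_panel()), gc$gene)
  expect_gt(gc$fold_change[gc$gene == "Gulp1"], 4)
  expect_identical(gc$call[gc$gene == "Gulp1"], "up")
  expect_lt(gc$p_bonf[gc$gene == "Gulp1"], 0.05)
})
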