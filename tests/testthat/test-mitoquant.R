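test_that("binarize_red applies a strict threshold", {
  m <- matrix(c(50, 200, 120, 99), 2, 2)   # [[50,120],[200,99]] row-wise
  out <- binarize_red(m, 100)
  expect_identical(out[, , 1], matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_true(all(!binarize_red(array(0, c(4, 4, 4)), 100)))
  # exactly-at-threshold stays background
  expect_false(binarize_red(matrix(100, 1, 1), 100)[1, 1, 1])
})

test_that("otsu resolves a bimodal histogram and flags constant images", {
  # equal-mass deltas at 10 and 200: compare against an exhaustive scan of
  # all 256 candidate thresholds
  v <- c(rep(10, 100), rep(200, 100))
  scan_best <- {
    best <- -Inf; arg <- NA
    for (t in 0:254) {
      w1 <- mean(v <= t); w2 <- 1 - w1
      if (w1 == 0 || w2 == 0) next
      sb <- w1 * w2 * (mean(v[v <= t]) - mean(v[v > t]))^2
      if (sb > best + 1e-12) { best <- sb; arg <- t }
    }
    arg
  }
  th <- otsu_threshold(v)
  expect_identical(th, as.numeric(scan_best))
  out <- binarize_red(array(v, c(10, 10, 2)), "otsu")
  expect_identical(which(out), which(array(v, c(10, 10, 2)) == 200))
  expect_warning(res <- binarize_red(array(7, c(4, 4, 2)), "otsu"), "constant")
  expect_true(all(!res))
})

test_that("the per-slice median filter takes the 3x3 majority", {
  # isolated voxel vanishes
  m <- array(FALSE, c(7, 7, 2)); m[4, 4, 1] <- TRUE
  expect_true(all(!median_filter_slices(m)))
  # an all-true slice is unchanged
  m2 <- array(TRUE, c(5, 5, 1))
  expect_true(all(median_filter_slices(m2)))
  # 5x5 plus sign (9 cells): hand-evaluating every 3x3 neighborhood shows the
  # four arm tips are removed (2 of 9 true), the center/arm-mid cells keep 5
  # of 9, and the four diagonal cells adjacent to two arms gain 5 of 9 — the
  # majority image is the central 3x3 block
  m3 <- array(FALSE, c(9, 9, 1))
  m3[5, 3:7, 1] <- TRUE; m3[3:7, 5, 1] <- TRUE
  got <- median_filter_slices(m3)
  want <- array(FALSE, c(9, 9, 1))
  want[4:6, 4:6, 1] <- TRUE
  expect_identical(got, want)
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    m <- array(runif(7^3) < 0.35, c(7, 7, 7))
    for (conn in c(6, 26)) {
      cs <- label_components_3d(m, conn)
      oracle <- oracle_flood_fill(m, conn)
      expect_true(same_partition(cs$label_volume, oracle))
    }
  }
  # labels are contiguous from 1 and deterministic in scan order
  m <- array(FALSE, c(5, 5, 1)); m[1, 1, 1] <- TRUE; m[4, 4, 1] <- TRUE
  cs <- label_components_3d(m, 26)
  expect_identical(vapply(cs$components, `[[`, integer(1), "id"), 1:2)
  expect_identical(cs$label_volume[1, 1, 1], 1L)
})

test_that("connectivity semantics separate corner-sharing voxels", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE
  expect_length(label_components_3d(m, 26)$components, 1L)
  expect_length(label_components_3d(m, 6)$components, 2L)
  expect_length(label_components_3d(array(FALSE, c(4, 4, 4)))$components, 0L)
})

test_that("enclosure follows the strict shell rule", {
  vs <- block_stack(c(10, 10, 10))
  vs$red[5:6, 5:6, 5:6] <- 255L
  cs <- label_components_3d(vs$red > 100, 26)
  rec <- test_enclosure(1, cs, vs$green, 100)
  expect_true(rec$enclosed)
  expect_identical(rec$failure_reason, "none")
  expect_identical(rec$shell_min_green, 255)

  # border contact on the z = 1 face
  vs2 <- block_stack(c(10, 10, 10))
  vs2$red[5:6, 5:6, 1:2] <- 255L
  cs2 <- label_components_3d(vs2$red > 100, 26)
  rec2 <- test_enclosure(1, cs2, vs2$green, 100)
  expect_false(rec2$enclosed)
  expect_identical(rec2$failure_reason, "border_contact")

  # a single shell voxel at exactly the threshold breaks enclosure (> 100
  # is strict)
  vs3 <- block_stack(c(10, 10, 10))
  vs3$red[5:6, 5:6, 5:6] <- 255L
  vs3$green[4, 5, 5] <- 100L
  cs3 <- label_components_3d(vs3$red > 100, 26)
  rec3 <- test_enclosure(1, cs3, vs3$green, 100)
  expect_false(rec3$enclosed)
  expect_identical(rec3$failure_reason, "shell_gap")
  expect_identical(rec3$shell_min_green, 100)
  expect_error(test_enclosure(99, cs3, vs3$green), "not present")
})

test_that("enclosure agrees with the exhaustive per-voxel oracle", {
  sim <- make_stack(dim = c(48, 48, 48), n_astrocytes = 1, n_enclosed = 3,
                    n_external = 3, n_border = 1, seed = 31)
  cs <- label_components_3d(median_filter_slices(sim$stack$red > 100), 26)
  for (cc in cs$components) {
    rec <- test_enclosure(cc$id, cs, sim$stack$green, 100)
    expect_identical(rec$enclosed,
                     oracle_enclosed(cs$label_volume, cc$id, sim$stack$green, 100))
  }
})

test_that("quantify_stack arithmetic matches the voxel bookkeeping", {
  vs <- block_stack(c(64, 64, 64))
  vs$red[30:31, 30:31, 30:31] <- 255L
  res <- quantify_stack(vs, red_threshold = 100, median_filter = FALSE)
  expect_equal(res$quant$astro_voxels, 64^3)
  expect_identical(res$quant$enclosed_mito_voxels, 8L)
  expect_equal(res$quant$incorporation_fraction_pct, 100 * 8 / 64^3)
  expect_equal(res$quant$enclosed_mito_volume_um3, 8 * 0.4^3)

  # no red signal: zero components, fraction 0
  empty <- quantify_stack(block_stack(c(16, 16, 16)), red_threshold = 100)
  expect_identical(empty$quant$n_components, 0L)
  expect_identical(empty$quant$incorporation_fraction_pct, 0)

  # no astrocyte signal: fraction undefined, not 0
  dark <- voxel_stack(array(0L, c(16, 16, 16)), array(0L, c(16, 16, 16)))
  dark$red[8, 8, 8] <- 255L
  expect_warning(res2 <- quantify_stack(dark, red_threshold = 100), "undefined")
  expect_true(is.na(res2$quant$incorporation_fraction_pct))
})

test_that("noise-free synthetic stacks are recovered perfectly", {
  sim <- make_stack(dim = c(64, 64, 64), n_astrocytes = 2, n_enclosed = 4,
                    n_external = 5, n_border = 2, seed = 19)
  q <- quantify_stack(sim$stack)
  rf <- recovered_flags(sim, q)
  expect_false(any(is.na(rf$match)))
  expect_identical(rf$detected, rf$planted)
})

test_that("raising the green threshold never makes a component enclosed", {
  sim <- make_stack(dim = c(48, 48, 48), n_astrocytes = 1, n_enclosed = 3,
                    n_external = 4, n_border = 1, noise_sd = 20, seed = 23)
  prev <- NULL
  for (thr in c(60, 100, 140, 179)) {
    q <- quantify_stack(sim$stack, green_threshold = thr, red_threshold = 100)
    enc <- q$enclosures$enclosed[order(q$enclosures$component_id)]
    if (!is.null(prev)) expect_true(all(enc <= prev))
    prev <- enc
  }
})

test_that("volumes scale as voxel_size^3 and padding leaves fractions alone", {
  sim <- make_stack(dim = c(48, 48, 48), n_astrocytes = 1, n_enclosed = 2,
                    n_external = 2, n_border = 0, seed = 29)
  q1 <- quantify_stack(sim$stack)
  big <- sim$stack; big$voxel_size_um <- 0.8
  q2 <- quantify_stack(big)
  expect_equal(q2$quant$astro_volume_um3, 8 * q1$quant$astro_volume_um3)
  expect_equal(q2$quant$incorporation_fraction_pct,
               q1$quant$incorporation_fraction_pct)
  expect_lte(q1$quant$enclosed_mito_voxels, sum(sim$stack$red > 100))

  # pad with background on the high faces: counts and fraction unchanged
  d <- dim(sim$stack$green); dp <- d + 6L
  g <- array(0L, dp); r <- array(0L, dp)
  g[1:d[1], 1:d[2], 1:d[3]] <- sim$stack$green
  r[1:d[1], 1:d[2], 1:d[3]] <- sim$stack$red
  q3 <- quantify_stack(voxel_stack(g, r))
  expect_identical(q3$quant$enclosed_mito_voxels, q1$quant$enclosed_mito_voxels)
  expect_equal(q3$quant$incorporation_fraction_pct,
               q1$quant$incorporation_fraction_pct)
})

test_that("astrocyte categories use the documented default bins", {
  expect_identical(as.character(classify_astrocyte(c(0, 3, 5, 6, 20, 21))),
                   c("none", "sporadic", "sporadic", "moderate", "moderate", "high"))
  expect_identical(as.character(classify_astrocyte(7, bins = c(0, 2, 6))), "high")
  expect_error(classify_astrocyte(-1))
})

test_that("cohort summaries report zero-incorporation percentages to 1 decimal", {
  rec <- data.frame(group = rep(c("control", "high_iop"), c(344, 339)),
                    enclosed_count = c(rep(0, 146), rep(3, 198),
                                       rep(0, 92), rep(8, 247)))
  s <- summarize_cohort(rec)
  expect_equal(s$per_group$pct_zero[s$per_group$group == "control"], 42.4)
  expect_equal(s$per_group$pct_zero[s$per_group$group == "high_iop"], 27.1)
  s2 <- summarize_cohort(data.frame(group = "g", enclosed_count = rep(3, 10)))
  expect_equal(s2$per_group$pct_zero, 0)
  expect_error(summarize_cohort(data.frame(group = character(),
                                           enclosed_count = numeric())),
               "at least one")
})
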