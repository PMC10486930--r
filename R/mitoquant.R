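# Quantification of axon-derived mitochondria enclosed by astrocyte
# cytoplasm in two-channel confocal stacks. The chain mirrors the original
# Matlab analysis: binarize the red channel, median-filter slice by slice
# with a 3 x 3 kernel, label 3D connected components, then keep the
# components completely surrounded by green signal above threshold.

#' Binarize the red (mitochondria) channel
#'
#' A voxel is foreground iff its intensity is strictly greater than the
#' threshold. `"otsu"` resolves to the 256-bin between-class-variance
#' maximizer for the stack at hand before the comparison; an intensity
#' threshold of 100 reproduces the fixed green-channel convention.
#'
#' @param red 8-bit array (2D or 3D).
#' @param threshold numeric intensity, or `"otsu"`.
#' @return logical array of the same dimensions.
#' @export
binarize_red <- function(red, threshold = "otsu") {
  red <- as_vol(red)
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(red)
    if (is.na(threshold)) {
      warning("constant image: Otsu threshold undefined, returning all-background mask")
      return(array(FALSE, dim(red)))
    }
  }
  red > threshold
}

#' 3 x 3 per-slice median filter of a binary mask
#'
#' Each voxel becomes the majority vote (>= 5 of 9) of its 3 x 3 in-plane
#' neighborhood; slices are filtered independently in xy, matching the 2D
#' kernel of the original analysis. Borders use replicate padding so true
#' objects at the image edge are not eroded by the padding itself.
#'
#' @param mask logical array (2D or 3D).
#' @return filtered logical array, same dimensions.
#' @export
median_filter_slices <- function(mask) {
  mask <- as_vol(mask)
  storage.mode(mask) <- "integer"
  d <- dim(mask)
  # replicate-pad in x and y
  px <- c(1L, seq_len(d[1]), d[1])
  py <- c(1L, seq_len(d[2]), d[2])
  pad <- mask[px, py, , drop = FALSE]
  acc <- array(0L, d)
  for (dx in 0:2) for (dy in 0:2)
    acc <- acc + pad[dx + seq_len(d[1]), dy + seq_len(d[2]), , drop = FALSE]
  acc >= 5L
}

#' Test whether a red component is enclosed by astrocyte cytoplasm
#'
#' A component counts as enclosed iff (a) none of its voxels lies on a stack
#' face (enclosure cannot be verified in all three dimensions for
#' border-contacting components) and (b) every voxel of its 1-voxel
#' 6-neighborhood shell — the face neighbors that are not part of the
#' component itself — has green intensity strictly greater than
#' `green_threshold`. Component-interior green values are not examined: the
#' red label may locally displace the cytoplasmic reporter signal.
#'
#' @param component_id component to test.
#' @param components a [label_components_3d()] result.
#' @param green green channel array matching the mask the components came from.
#' @param green_threshold intensity cutoff (default 100).
#' @return a list (`enclosure_record`): `component_id`, `enclosed`,
#'   `failure_reason` (`"none"`, `"border_contact"` or `"shell_gap"`),
#'   `shell_min_green` (NA when border contact pre-empts the shell scan).
#' @export
test_enclosure <- function(component_id, components, green, green_threshold = 100) {
  stopifnot(inherits(components, "component_set"))
  green <- as_vol(green)
  comp <- NULL
  for (cc in components$components) if (cc$id == component_id) { comp <- cc; break }
  if (is.null(comp)) stop_gq("component id %s not present", component_id)
  d <- components$dim
  vox <- comp$voxels
  rec <- function(enclosed, reason, shell_min)
    list(component_id = component_id, enclosed = enclosed,
         failure_reason = reason, shell_min_green = shell_min)
  on_face <- any(vox[, 1] == 1L | vox[, 1] == d[1] |
                 vox[, 2] == 1L | vox[, 2] == d[2] |
                 vox[, 3] == 1L | vox[, 3] == d[3])
  if (on_face) return(rec(FALSE, "border_contact", NA_real_))
  offs <- conn_offsets(6)
  nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    cbind(vox[, 1] + offs[i, 1], vox[, 2] + offs[i, 2], vox[, 3] + offs[i, 3])))
  lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
  lin <- unique(lin)
  shell <- lin[components$label_volume[lin] != component_id]
  smin <- min(green[shell])
  if (smin > green_threshold) rec(TRUE, "none", smin) else rec(FALSE, "shell_gap", smin)
}

#' Quantify a two-channel stack
#'
#' Runs the full per-stack chain: binarize the red channel, 3 x 3 per-slice
#' median filter, 3D component labeling, per-component enclosure test, and
#' volume bookkeeping. The astrocyte volume is the count of green voxels
#' strictly above `green_threshold`; the incorporated mitochondria volume is
#' the summed voxel count of enclosed components. The incorporation fraction
#' is reported in percent of the astrocyte volume and is `NA` (undefined,
#' with a warning) when the stack contains no astrocyte signal — not 0, to
#' avoid silently deflating group medians.
#'
#' @param stack a [voxel_stack()].
#' @param green_threshold green intensity cutoff for cytoplasm (default 100).
#' @param red_threshold red binarization threshold, or `"otsu"` (default).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_voxels drop components smaller than this before testing
#'   (default 0: no size filter).
#' @param median_filter apply the 3 x 3 per-slice filter (default TRUE).
#' @return list with `quant` (class `stack_quant`: `astro_voxels`,
#'   `astro_volume_um3`, `enclosed_mito_voxels`, `enclosed_mito_volume_um3`,
#'   `incorporation_fraction_pct`, `n_components`, `n_enclosed`),
#'   `enclosures` (data.frame of per-component records) and `components`.
#' @export
quantify_stack <- function(stack, green_threshold = 100, red_threshold = "otsu",
                           connectivity = 26, min_voxels = 0,
                           median_filter = TRUE) {
  stopifnot(inherits(stack, "voxel_stack"))
  mask <- binarize_red(stack$red, red_threshold)
  if (median_filter) mask <- median_filter_slices(mask)
  cs <- label_components_3d(mask, connectivity)
  if (min_voxels > 0) {
    keep <- vapply(cs$components, function(cc) cc$voxel_count >= min_voxels, logical(1))
    cs$components <- cs$components[keep]
  }
  recs <- lapply(cs$components, function(cc)
    test_enclosure(cc$id, cs, stack$green, green_threshold))
  enc <- data.frame(
    component_id = vapply(cs$components, `[[`, integer(1), "id"),
    voxel_count = vapply(cs$components, `[[`, integer(1), "voxel_count"),
    enclosed = vapply(recs, `[[`, logical(1), "enclosed"),
    failure_reason = vapply(recs, `[[`, character(1), "failure_reason"),
    shell_min_green = vapply(recs, `[[`, numeric(1), "shell_min_green"))
  astro_vox <- sum(stack$green > green_threshold)
  mito_vox <- sum(enc$voxel_count[enc$enclosed])
  vs3 <- stack$voxel_size_um^3
  frac <- if (astro_vox > 0) 100 * mito_vox / astro_vox else {
    warning("stack contains no astrocyte signal: incorporation fraction undefined")
    NA_real_
  }
  quant <- structure(list(
    astro_voxels = astro_vox, astro_volume_um3 = astro_vox * vs3,
    enclosed_mito_voxels = mito_vox, enclosed_mito_volume_um3 = mito_vox * vs3,
    incorporation_fraction_pct = frac,
    n_components = nrow(enc), n_enclosed = sum(enc$enclosed)),
    class = "stack_quant")
  list(quant = quant, enclosures = enc, components = cs)
}

#' @export
print.stack_quant <- function(x, ...) {
  cat(sprintf(paste0(
    "stack_quant: %d/%d components enclosed; astrocyte volume %.1f um^3;\n",
    "  incorporated mitochondria %.2f um^3 (%s%% of astrocyte volume)\n"),
    x$n_enclosed, x$n_components, x$astro_volume_um3,
    x$enclosed_mito_volume_um3,
    if (is.na(x$incorporation_fraction_pct)) "NA"
    else format(x$incorporation_fraction_pct, digits = 3)))
  invisible(x)
}

#' Classify an astrocyte by its count of incorporated mitochondria
#'
#' Default bins reproduce the four qualitative categories used for single
#' cells (none / sporadic / moderate / high): 0, 1-5, 6-20, > 20. The count
#' thresholds are a package choice (the original report shows the categories
#' but prints no cutoffs); `bins` are the inclusive upper edges of the first
#' three categories.
#'
#' @param enclosed_count integer vector of per-astrocyte mitochondria counts.
#' @param bins strictly increasing inclusive upper edges, default `c(0, 5, 20)`.
#' @param labels category labels.
#' @return factor with levels `labels`.
#' @export
classify_astrocyte <- function(enclosed_count, bins = c(0L, 5L, 20L),
                               labels = c("none", "sporadic", "moderate", "high")) {
  stopifnot(all(enclosed_count >= 0), all(diff(bins) > 0),
            length(labels) == length(bins) + 1L)
  idx <- findInterval(enclosed_count, bins + 1L) + 1L  # count <= bins[k] -> k
  factor(labels[idx], levels = labels)
}

#' Cohort summary of per-astrocyte incorporation
#'
#' Per group: number of astrocytes, number and percentage (1 decimal) with
#' zero incorporated mitochondria, and the none/sporadic/moderate/high
#' category distribution.
#'
#' @param records data.frame with columns `group` and `enclosed_count`
#'   (one row per astrocyte).
#' @param bins,labels passed to [classify_astrocyte()].
#' @return list (`cohort_summary`) with `per_group` data.frame and
#'   `categories` (groups x categories count table).
#' @examples
#' rec <- data.frame(group = rep(c("saline", "microbead"), c(4, 4)),
#'                   enclosed_count = c(0, 0, 2, 7, 0, 3, 9, 25))
#' summarize_cohort(rec)
#' @export
summarize_cohort <- function(records, bins = c(0L, 5L, 20L),
                             labels = c("none", "sporadic", "moderate", "high")) {
  stopifnot(is.data.frame(records), all(c("group", "enclosed_count") %in% names(records)))
  records$group <- factor(records$group)
  if (any(table(records$group) == 0L) || nrow(records) == 0L)
    stop_gq("every group needs at least one astrocyte")
  cat_f <- classify_astrocyte(records$enclosed_count, bins, labels)
  per_group <- do.call(rbind, lapply(levels(records$group), function(g) {
    cnt <- records$enclosed_count[records$group == g]
    data.frame(group = g, n = length(cnt), n_zero = sum(cnt == 0),
               pct_zero = round(100 * sum(cnt == 0) / length(cnt), 1))
  }))
  structure(list(per_group = per_group,
                 categories = table(group = records$group, category = cat_f)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary: astrocytes with zero incorporated mitochondria\n")
  print(x$per_group, row.names = FALSE)
  cat("\ncategory distribution:\n")
  print(x$categories)
  invisible(x)
}
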