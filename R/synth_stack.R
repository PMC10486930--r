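# Synthetic two-channel confocal stacks with known ground truth.
#
# The generator emulates the imaging substrate of the transcellular
# mitophagy assay: stochastically labeled astrocytes (green; soma =
# ellipsoid, 4-8 tubular processes grown as jittered random walks) and
# punctate mitochondria (red; small ellipsoids) planted in three classes
# with recorded truth:
#   enclosed  - all punctum voxels AND the full 1-voxel 6-neighborhood shell
#               inside an astrocyte mask, off the stack border;
#   external  - punctum and shell entirely outside every astrocyte mask;
#   border    - punctum centered on a z face of the stack.
# On a noise-free stack the enclosure detector must reproduce these flags
# exactly; all placement rules below exist to make that guarantee hold even
# through the 3 x 3 per-slice median filter (puncta have in-plane radii
# >= 1.5 voxels so each occupied slice keeps its center voxel; classes are
# separated by a >= 2 voxel Chebyshev gap so components never merge).

mark_ellipsoid <- function(arr, center, radii, clip = TRUE) {
  d <- dim(arr)
  lo <- pmax(1L, floor(center - radii)); hi <- pmin(d, ceiling(center + radii))
  if (any(lo > hi)) return(arr)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  fx <- ((xs - center[1]) / radii[1])^2
  fy <- ((ys - center[2]) / radii[2])^2
  fz <- ((zs - center[3]) / radii[3])^2
  inside <- outer(outer(fx, fy, `+`), fz, `+`) <= 1
  arr[xs, ys, zs] <- arr[xs, ys, zs] | inside
  arr
}

ellipsoid_voxels <- function(center, radii, d) {
  lo <- pmax(1L, floor(center - radii)); hi <- pmin(d, ceiling(center + radii))
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  keep <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
          ((g$z - center[3]) / radii[3])^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

shell6 <- function(vox, d) {
  offs <- conn_offsets(6)
  nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    cbind(vox[, 1] + offs[i, 1], vox[, 2] + offs[i, 2], vox[, 3] + offs[i, 3])))
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
           nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
  nb <- unique(nb)
  key <- function(m) m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
  nb[!(key(nb) %in% key(vox)), , drop = FALSE]
}

lin_idx <- function(vox, d) vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]

grow_astrocyte <- function(mask, d) {
  margin <- pmax(4, round(d * 0.12))
  center <- vapply(1:3, function(k) runif(1, margin[min(k, length(margin))],
                                          d[k] - margin[min(k, length(margin))]), numeric(1))
  soma <- pmax(6, round(d * c(0.16, 0.14, 0.12) * runif(3, 0.9, 1.15)))
  mask <- mark_ellipsoid(mask, center, soma)
  n_proc <- sample(4:8, 1)
  for (p in seq_len(n_proc)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- center + dir * soma * 0.6
    r <- runif(1, 2.5, 3.5)
    steps <- sample(round(min(d) * 0.25):round(min(d) * 0.45), 1)
    for (s in seq_len(steps)) {
      dir <- dir + rnorm(3, sd = 0.25); dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * 1.5
      if (any(pos < 2) || any(pos > d - 1)) break
      mask <- mark_ellipsoid(mask, pos, rep(r, 3))
    }
  }
  mask
}

#' Generate a synthetic two-channel stack with planted mitochondria truth
#'
#' Builds a voxel stack emulating the in-vivo assay: the green channel is an
#' astrocyte cytoplasm reporter (above `green_level` inside the cell masks,
#' background elsewhere), the red channel holds punctate mitochondria planted
#' in three classes with recorded ground truth (see the class definitions in
#' the source header). Identical `(parameters, seed)` give byte-identical
#' output; an impossible placement request (e.g. an enclosed punctum that
#' cannot fit inside any astrocyte) raises an error rather than silently
#' planting fewer objects.
#'
#' @param dim stack dimensions in voxels (length 3, each >= 16).
#' @param n_astrocytes number of labeled astrocytes (>= 0).
#' @param n_enclosed,n_external,n_border punctum counts per class (>= 0).
#'   When `n_astrocytes = 0`, enclosed puncta are unplaceable.
#' @param noise_sd additive Gaussian noise sigma on both channels
#'   (clipped to 0..255; default 0 for exact ground truth).
#' @param voxel_size_um isotropic voxel size (default 0.4).
#' @param green_level,red_level foreground intensities (defaults 180, 230).
#' @param mito_radius punctum semi-axis range in voxels (default `c(1.5, 3)`).
#' @param seed RNG seed (required; generators leave global RNG state alone).
#' @return list with `stack` (a [voxel_stack()]) and `truth` (class
#'   `stack_truth`): `astro_masks` (list of linear-index vectors),
#'   `mito_records` (data.frame: `id`, `class`, `planted_enclosed`,
#'   `voxel_count`; voxel coordinates in attribute `voxels`),
#'   `voxel_size_um`.
#' @examples
#' sim <- make_stack(dim = c(48, 48, 48), n_astrocytes = 1,
#'                   n_enclosed = 2, n_external = 2, seed = 1)
#' sim$truth$mito_records
#' @export
make_stack <- function(dim = c(64, 64, 64), n_astrocytes = 2,
                       n_enclosed = 4, n_external = 8, n_border = 2,
                       noise_sd = 0, voxel_size_um = 0.4,
                       green_level = 180, red_level = 230,
                       mito_radius = c(1.5, 3), seed) {
  d <- as.integer(dim)
  if (length(d) != 3L || any(d < 16L)) stop_gq("dim must be three values >= 16")
  stopifnot(n_astrocytes >= 0, n_enclosed >= 0, n_external >= 0, n_border >= 0,
            noise_sd >= 0, green_level > 100)
  if (missing(seed)) stop_gq("make_stack() requires an explicit seed")
  with_seed(seed, {
    mask <- array(FALSE, d)
    astro_masks <- vector("list", n_astrocytes)
    for (a in seq_len(n_astrocytes)) {
      before <- mask
      mask <- grow_astrocyte(mask, d)
      astro_masks[[a]] <- which(mask & !before)
    }
    occupied <- array(FALSE, d)    # puncta dilated by 1 (Chebyshev)
    red <- array(0L, d)
    records <- list(); voxsets <- list()
    mask_co <- arrayInd(which(mask), d)
    place <- function(class, n_target) {
      if (class == "enclosed" && n_target > 0 && nrow(mask_co) == 0L)
        stop_gq("cannot place enclosed mitochondria without an astrocyte")
      placed <- 0L
      while (placed < n_target) {
        ok <- FALSE
        for (try in 1:400) {
          shrink <- if (try > 200) 0.7 else 1
          r <- pmax(1.5, runif(3, mito_radius[1], mito_radius[2]) * shrink)
          if (class == "border") {
            ctr <- c(runif(1, r[1] + 2, d[1] - r[1] - 2),
                     runif(1, r[2] + 2, d[2] - r[2] - 2),
                     if (runif(1) < 0.5) 1 else d[3])
          } else if (class == "enclosed") {
            # candidate centers drawn from the astrocyte mask itself: the
            # full punctum + shell condition below does the real filtering
            ctr <- mask_co[sample.int(nrow(mask_co), 1), ] + runif(3, -0.5, 0.5)
          } else {
            ctr <- c(runif(1, r[1] + 2, d[1] - r[1] - 2),
                     runif(1, r[2] + 2, d[2] - r[2] - 2),
                     runif(1, r[3] + 2, d[3] - r[3] - 2))
          }
          vox <- ellipsoid_voxels(ctr, r, d)
          if (nrow(vox) == 0L) next
          sh <- shell6(vox, d)
          inside_mask <- mask[lin_idx(vox, d)]
          shell_in <- mask[lin_idx(sh, d)]
          in_core <- all(vox[, 1] >= 2 & vox[, 1] <= d[1] - 1 &
                         vox[, 2] >= 2 & vox[, 2] <= d[2] - 1 &
                         vox[, 3] >= 2 & vox[, 3] <= d[3] - 1)
          on_face <- !in_core &&
            any(vox[, 1] == 1 | vox[, 1] == d[1] | vox[, 2] == 1 |
                vox[, 2] == d[2] | vox[, 3] == 1 | vox[, 3] == d[3])
          good <- switch(class,
            enclosed = in_core && all(inside_mask) && all(shell_in),
            external = in_core && !any(inside_mask) && !any(shell_in),
            border = on_face)
          if (!good) next
          # >= 2 voxel Chebyshev separation from every other punctum
          dil <- unique(rbind(vox, do.call(rbind, lapply(
            seq_len(nrow(conn_offsets(26))), function(i) {
              o <- conn_offsets(26)[i, ]
              cbind(vox[, 1] + o[1], vox[, 2] + o[2], vox[, 3] + o[3])
            }))))
          dil <- dil[dil[, 1] >= 1 & dil[, 1] <= d[1] & dil[, 2] >= 1 &
                     dil[, 2] <= d[2] & dil[, 3] >= 1 & dil[, 3] <= d[3], , drop = FALSE]
          if (any(occupied[lin_idx(dil, d)])) next
          occupied[lin_idx(dil, d)] <<- TRUE
          red[lin_idx(vox, d)] <<- red_level
          placed <- placed + 1L
          id <- length(records) + 1L
          records[[id]] <<- data.frame(id = id, class = class,
                                       planted_enclosed = (class == "enclosed"),
                                       voxel_count = nrow(vox))
          voxsets[[id]] <<- vox
          ok <- TRUE
          break
        }
        if (!ok)
          stop_gq("could not place a %s mitochondrion (astrocyte too thin or stack too crowded)", class)
      }
    }
    place("enclosed", n_enclosed)
    place("external", n_external)
    place("border", n_border)
    green <- array(0, d)
    green[mask] <- green_level
    if (noise_sd > 0) {
      green <- green + rnorm(length(green), 0, noise_sd)
      red <- red + rnorm(length(red), 0, noise_sd)
    }
    clip8 <- function(x) { x <- round(x); x[x < 0] <- 0; x[x > 255] <- 255; storage.mode(x) <- "integer"; x }
    stack <- voxel_stack(clip8(green), clip8(red), voxel_size_um)
    mr <- if (length(records)) do.call(rbind, records) else
      data.frame(id = integer(), class = character(),
                 planted_enclosed = logical(), voxel_count = integer())
    attr(mr, "voxels") <- voxsets
    truth <- structure(list(astro_masks = astro_masks, mito_records = mr,
                            voxel_size_um = voxel_size_um),
                       class = "stack_truth")
    list(stack = stack, truth = truth)
  })
}

#' Match detected components to planted mitochondria
#'
#' Assigns each detected component to the planted punctum that contains its
#' first voxel (detected components are subsets of planted puncta on
#' noise-free stacks, up to median-filter erosion).
#'
#' @param components a [label_components_3d()] result.
#' @param truth a `stack_truth` from [make_stack()].
#' @return integer vector: planted record id per component (NA if unmatched).
#' @export
match_planted <- function(components, truth) {
  voxsets <- attr(truth$mito_records, "voxels")
  d <- components$dim
  keys <- lapply(voxsets, lin_idx, d = d)
  vapply(components$components, function(cc) {
    k <- lin_idx(cc$voxels, d)
    hit <- which(vapply(keys, function(pk) all(k %in% pk), logical(1)))
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1))
}
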