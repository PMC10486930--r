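# Synthetic retinal fields of ganglion-cell nuclei.
#
# Nuclei are placed by a Poisson process (count ~ Poisson(density * area))
# with an optional minimum center spacing, rendered as bright disks that are
# never clipped by the field border, on a dim background. Defaults: ~8 um
# nuclei (Brn3a-stained ganglion cell somata) at 1 um/pixel in a 0.1 mm^2
# field; mouse ganglion cell density is on the order of 3000-4000 per mm^2.

#' Generate a synthetic retinal field with a known nucleus count
#'
#' @param density nuclei per mm^2 (>= 0); ignored when `n_nuclei` is given.
#' @param field_area_mm2 field area (the image is square; default 0.1 mm^2).
#' @param n_nuclei plant exactly this many nuclei instead of a Poisson draw.
#' @param pixel_size_um pixel edge (default 1).
#' @param radius_um nucleus disk radius (default 4).
#' @param min_spacing_um minimum center-to-center spacing (default
#'   `2 * radius_um + 2`: non-touching disks). Infeasible packing after
#'   exhausting placement attempts raises an error.
#' @param fg_level,bg_level disk and background intensities (200, 20).
#' @param noise_sd additive Gaussian noise sigma (default 0).
#' @param seed RNG seed (required).
#' @return list with `image` (integer matrix), `true_count`, `centers`
#'   (n x 2, pixels), `field_area_mm2`, `pixel_size_um`.
#' @examples
#' f <- make_retina_field(density = 500, seed = 1)
#' f$true_count
#' @export
make_retina_field <- function(density = 3500, field_area_mm2 = 0.1,
                              n_nuclei = NULL, pixel_size_um = 1,
                              radius_um = 4,
                              min_spacing_um = 2 * radius_um + 2,
                              fg_level = 200, bg_level = 20,
                              noise_sd = 0, seed) {
  stopifnot(density >= 0, field_area_mm2 > 0, radius_um > 0)
  if (missing(seed)) stop_gq("make_retina_field() requires an explicit seed")
  side_um <- sqrt(field_area_mm2) * 1000
  npx <- max(16L, round(side_um / pixel_size_um))
  r_px <- radius_um / pixel_size_um
  spacing_px <- min_spacing_um / pixel_size_um
  with_seed(seed, {
    n <- as.integer(n_nuclei %||% rpois(1, density * field_area_mm2))
    centers <- matrix(numeric(0), 0, 2)
    margin <- r_px + 1              # disks never clipped by the border
    tries <- 0L
    while (nrow(centers) < n) {
      if (tries > 200 * max(n, 1))
        stop_gq("cannot pack %d nuclei at %.1f um spacing into the field", n, min_spacing_um)
      tries <- tries + 1L
      p <- runif(2, margin, npx - margin)
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) < spacing_px) next
      centers <- rbind(centers, p)
    }
    img <- matrix(bg_level, npx, npx)
    if (n > 0) {
      xs <- row(img); ys <- col(img)
      for (k in seq_len(n)) {
        sel <- (xs - centers[k, 1])^2 + (ys - centers[k, 2])^2 <= r_px^2
        img[sel] <- fg_level
      }
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    list(image = img, true_count = n, centers = centers,
         field_area_mm2 = field_area_mm2, pixel_size_um = pixel_size_um)
  })
}
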