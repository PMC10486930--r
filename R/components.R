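# 3D connected-component labeling of binary volumes.

conn_offsets <- function(connectivity, two_d = FALSE) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = if (two_d) 0L else -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)),
                 "4" = ord == 1, "8" = rep(TRUE, nrow(g)),
                 stop_gq("connectivity must be one of 6, 18, 26 (3D) or 4, 8 (2D)"))
  as.matrix(g[keep, , drop = FALSE])
}

#' Label connected components of a binary volume
#'
#' Partitions the foreground of a 3D binary mask into connected components
#' (the mitochondria candidates of the red channel). Connectivity 6 links
#' face neighbors, 18 adds edge neighbors, 26 adds corner neighbors
#' (the usual default for 3D labeling). Labels are contiguous from 1 and
#' ordered by each component's first foreground voxel in array (column-major)
#' scan order, so labeling is fully deterministic.
#'
#' @param mask logical (or 0/1) array, 2D or 3D.
#' @param connectivity 6, 18 or 26 (for a 2D mask, 6 means 4-connectivity and
#'   18/26 mean 8-connectivity).
#' @return an object of class `component_set`: list with `label_volume`
#'   (integer array, 0 = background), `components` (list of per-component
#'   lists: `id`, `voxels` (n x 3 coordinate matrix), `voxel_count`),
#'   `connectivity`, `dim`.
#' @examples
#' m <- array(FALSE, c(4, 4, 1)); m[1, 1, 1] <- m[3, 3, 1] <- TRUE
#' label_components_3d(m, 26)$components
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  mask <- as_vol(mask)
  storage.mode(mask) <- "logical"
  d <- dim(mask)
  fg <- which(mask)
  n_fg <- length(fg)
  out <- structure(list(label_volume = array(0L, d), components = list(),
                        connectivity = connectivity, dim = d),
                   class = "component_set")
  if (n_fg == 0L) return(out)
  rank_of <- integer(prod(d))          # linear index -> foreground rank
  rank_of[fg] <- seq_len(n_fg)
  co <- arrayInd(fg, d)
  offs <- conn_offsets(connectivity, two_d = d[3] == 1L)
  # half set of offsets suffices for an undirected adjacency graph
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- cbind(co[, 1] + offs[i, 1], co[, 2] + offs[i, 2], co[, 3] + offs[i, 3])
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- rank_of[lin] > 0L
    if (!any(hit)) next
    edges[[i]] <- rbind(which(ok)[hit], rank_of[lin[hit]])
  }
  em <- do.call(cbind, edges)
  memb <- if (is.null(em)) {
    seq_len(n_fg)
  } else {
    g <- igraph::make_graph(edges = as.vector(em), n = n_fg, directed = FALSE)
    igraph::components(g)$membership
  }
  # relabel so labels follow the scan order of each component's first voxel
  first <- vapply(split(seq_len(n_fg), memb), min, integer(1))
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  lab <- relab[memb]
  lv <- array(0L, d)
  lv[fg] <- lab
  comps <- lapply(split(seq_len(n_fg), lab), function(ix)
    list(id = lab[ix[1]], voxels = co[ix, , drop = FALSE],
         voxel_count = length(ix)))
  names(comps) <- NULL
  out$label_volume <- lv
  out$components <- comps
  out
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d components (connectivity %s) in a %s volume\n",
              length(x$components), x$connectivity,
              paste(x$dim, collapse = " x ")))
  invisible(x)
}
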