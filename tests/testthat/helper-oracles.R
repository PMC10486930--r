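# Independent oracles, deliberately written with different algorithms than
# the package implementation.

# Recursive (stack-based) flood fill over a 3D logical mask; returns an
# integer label volume. Independent of the igraph-based labeling path.
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)),
    "26" = {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      g[rowSums(abs(g)) > 0, , drop = FALSE]
    },
    stop("oracle supports connectivity 6 and 26"))
  lab <- array(0L, d)
  nextlab <- 0L
  for (i in seq_len(prod(d))) {
    if (!mask[i] || lab[i] > 0L) next
    nextlab <- nextlab + 1L
    queue <- list(arrayInd(i, d)[1, ])
    lab[i] <- nextlab
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        li <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nextlab
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# partitions are equal up to label naming
same_partition <- function(lab1, lab2) {
  f1 <- lab1[lab1 > 0 | lab2 > 0]; f2 <- lab2[lab1 > 0 | lab2 > 0]
  if (any(xor(f1 == 0, f2 == 0))) return(FALSE)
  length(unique(paste(f1, f2))) == length(unique(f1)) &&
    length(unique(paste(f1, f2))) == length(unique(f2))
}

# two-sided exact Wilcoxon p by direct enumeration of group assignments
# (values, not ranks, are re-partitioned: a genuinely different route than
# the implementation's rank-sum enumeration)
oracle_wilcox_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  stat <- function(idx) sum(r[idx])
  obs <- stat(seq_len(na))
  combs <- utils::combn(n, na)
  all_w <- apply(combs, 2, stat)
  mu <- mean(all_w)
  mean(abs(all_w - mu) >= abs(obs - mu) - 1e-9)
}

# OLS via the normal equations (X'X)^-1 X'y
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))   # (intercept, slope)
}

# enclosure by exhaustive per-voxel shell check against a label volume
oracle_enclosed <- function(label_volume, id, green, thr = 100) {
  d <- dim(label_volume)
  vox <- which(label_volume == id, arr.ind = TRUE)
  for (k in seq_len(nrow(vox))) {
    p <- vox[k, ]
    if (any(p == 1) || any(p == d)) return(FALSE)
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      q <- p + o
      if (label_volume[q[1], q[2], q[3]] == id) next
      if (green[q[1], q[2], q[3]] <= thr) return(FALSE)
    }
  }
  TRUE
}
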