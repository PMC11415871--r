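# Brute-force reference implementations of the geometric operators.
# Deliberately naive (exhaustive scans, BFS, pairwise exact distances) and
# independent of the package's compiled kernels.

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

# BFS connected-component labelling
bf_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  off <- neighbour_offsets(connectivity)
  lab <- array(0L, dm)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      z <- (v - 1) %/% (dm[1] * dm[2])
      r <- (v - 1) %% (dm[1] * dm[2])
      y <- r %/% dm[1]; x <- r %% dm[1]
      for (o in seq_len(nrow(off))) {
        xx <- x + off[o, 1]; yy <- y + off[o, 2]; zz <- z + off[o, 3]
        if (xx < 0 || xx >= dm[1] || yy < 0 || yy >= dm[2] ||
            zz < 0 || zz >= dm[3]) next
        w <- 1 + xx + dm[1] * (yy + dm[2] * zz)
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# exact pairwise Euclidean distance transform
bf_edt <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  out <- array(0, dm)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(out)
  if (nrow(bg) == 0) { out[mask] <- Inf; return(out) }
  bgs <- sweep(bg, 2, spacing, `*`)
  fgs <- sweep(fg, 2, spacing, `*`)
  d <- apply(fgs, 1, function(p) {
    sqrt(min((bgs[, 1] - p[1])^2 + (bgs[, 2] - p[2])^2 + (bgs[, 3] - p[3])^2))
  })
  out[mask] <- d
  out
}

# hole fill: background BFS from the border (6-connected complement)
bf_fill_holes <- function(mask) {
  dm <- dim(mask)
  bg <- bf_components(!mask, connectivity = 6)
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE
  border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  outside <- unique(bg[border & bg > 0L])
  mask | (bg > 0L & !(bg %in% outside))
}

# dilation by exhaustive distance check
bf_dilate <- function(mask, radius, spacing = c(1, 1, 1)) {
  d <- bf_edt(!mask, spacing)
  out <- mask | (d <= radius + 1e-9)
  array(out, dim(mask))
}

# does any component hold >= min_cross voxels strictly on each side of the
# world x = 0 plane?
bf_crosses_midline <- function(mask, affine, connectivity, min_cross) {
  lab <- bf_components(mask, connectivity)
  if (!any(mask)) return(FALSE)
  idx <- which(mask, arr.ind = TRUE)
  xw <- affine[1, 1] * (idx[, 1] - 1) + affine[1, 2] * (idx[, 2] - 1) +
    affine[1, 3] * (idx[, 3] - 1) + affine[1, 4]
  comp <- lab[mask]
  for (k in unique(comp)) {
    xs <- xw[comp == k]
    if (sum(xs < -1e-9) >= min_cross && sum(xs > 1e-9) >= min_cross)
      return(TRUE)
  }
  FALSE
}

# confusion-matrix recomputation of kappa (direct formula, not the
# disagreement form used by the package)
bf_kappa <- function(x, y, weighting = "none", categories = sort(unique(c(x, y)))) {
  k <- length(categories)
  xi <- match(x, categories); yi <- match(y, categories)
  O <- matrix(0, k, k)
  for (i in seq_along(xi)) O[xi[i], yi[i]] <- O[xi[i], yi[i]] + 1
  O <- O / length(xi)
  E <- rowSums(O) %o% colSums(O)
  W <- if (k == 1) matrix(1, 1, 1) else if (weighting == "linear") {
    1 - abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  } else diag(k)
  po <- sum(W * O); pe <- sum(W * E)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

bf_balanced_accuracy <- function(truth, pred) {
  mean(sapply(unique(truth), function(cl) mean(pred[truth == cl] == cl)))
}

random_mask <- function(shape, p = 0.3) {
  array(runif(prod(shape)) < p, shape)
}
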