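# Small binary-morphology helpers shared by the phantom generator, the
# default background construction and the zone-length matrix.

# Shift a 3D array by one voxel along `axis` in direction `dir` (+1/-1),
# filling the vacated slab with `fill`.
shift_array <- function(arr, axis, dir, fill = FALSE) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  src <- idx
  if (dir > 0) src[[axis]] <- c(1L, seq_len(d[axis] - 1L))
  else         src[[axis]] <- c(seq_len(d[axis] - 1L) + 1L, d[axis])
  out <- do.call(`[`, c(list(arr), src, list(drop = FALSE)))
  edge <- idx
  edge[[axis]] <- if (dir > 0) 1L else d[axis]
  out <- array(out, d)
  out[edge[[1]], edge[[2]], edge[[3]]] <- fill
  out
}

#' Binary mask dilation
#'
#' Dilates a 3D logical mask with a 6-connected structuring element,
#' repeated \code{iterations} times. Used, e.g., to turn a tight tumor
#' mask into a generous manual-VOI stand-in or to build the background
#' shell for the adaptive threshold.
#'
#' @param mask logical 3D array.
#' @param iterations number of one-voxel dilation passes.
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  out <- mask != 0
  for (it in seq_len(iterations)) {
    acc <- out
    for (axis in 1:3) for (dir in c(-1L, 1L))
      acc <- acc | shift_array(out, axis, dir)
    out <- acc
  }
  out
}

# The 13 unique 3D direction offsets at Chebyshev distance 1 (one of each
# antipodal pair); the full 26-neighbourhood is these plus their negatives.
directions_13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(d, 1, function(v) v[which(v != 0)[1]] > 0)
  unname(d[keep, , drop = FALSE])
}

# Label 26-connected components of `mask` restricted to voxels where
# `values` is equal. `values` may be NULL (plain connectivity). Returns an
# integer array, 0 outside the mask, component ids 1..k inside.
label_components <- function(mask, values = NULL) {
  d <- dim(mask)
  vox <- which(mask)
  n <- length(vox)
  lab <- array(0L, d)
  if (n == 0L) return(lab)
  pos <- integer(prod(d))      # linear voxel -> index in `vox`
  pos[vox] <- seq_len(n)
  ijk <- arrayInd(vox, d)
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  dirs <- directions_13()
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    nb <- sweep(ijk, 2, off, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    j <- pos[lin]
    i <- which(ok)[j > 0]
    j <- j[j > 0]
    if (!is.null(values)) {
      same <- values[vox[i]] == values[vox[j]]
      i <- i[same]; j <- j[same]
    }
    for (e in seq_along(i)) {
      ri <- find(i[e]); rj <- find(j[e])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab[vox] <- match(roots, unique(roots))
  lab
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
gaussian_smooth <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, 3L)
  out <- arr
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    n <- d[axis]
    x <- seq_len(n)
    K <- exp(-0.5 * (outer(x, x, `-`) / s)^2)
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(out, perm)
    dim(m) <- c(n, prod(d[perm[2:3]]))
    m <- K %*% m
    dim(m) <- d[perm]
    out <- aperm(m, order(perm))
  }
  out
}
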