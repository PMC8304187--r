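#' Build the four texture matrices of a discretized tumor
#'
#' \describe{
#'   \item{GLCM}{grey-level co-occurrence counts over the 13 unique 3D
#'     directions at voxel distance 1. Each in-mask voxel pair contributes
#'     symmetrically; by default the 13 directional matrices are summed
#'     before normalization (merged strategy); the per-direction matrices
#'     are kept so features can alternatively be averaged per direction.}
#'   \item{NGLDM}{neighbourhood grey-level difference vector: for each
#'     in-mask voxel, the absolute difference between its level and the mean
#'     level of its in-mask 26-neighbours, accumulated per level.}
#'   \item{GLRLM}{run-length matrices, one per direction: maximal straight
#'     runs of equal level; features are computed per direction and averaged
#'     over the 13 directions.}
#'   \item{GLZLM}{zone-length matrix: 26-connected components of equal level
#'     (zones), one count per zone at its (level, size) cell.}
#' }
#'
#' @param disc a [discretize()]d VOI with at least 2 voxels.
#' @return A list of class \code{texture_matrices}: \code{glcm} (L x L
#'   merged counts), \code{glcm_dir} (list of 13 L x L count matrices),
#'   \code{ngldm} (list \code{s}, \code{n} of length L), \code{glrlm}
#'   (list of 13 L x max-run count matrices), \code{glzlm} (L x max-zone
#'   counts), \code{n_levels}, \code{n_voxels}.
#' @export
build_texture_matrices <- function(disc) {
  stopifnot(inherits(disc, "discretized_voi"))
  g <- disc$levels
  mask <- disc$mask
  L <- disc$n_levels
  d <- dim(g)
  n_vox <- sum(mask)
  if (n_vox < 2L) stop("texture matrices need at least 2 voxels")
  dirs <- directions_13()
  lin <- which(mask)
  ijk <- arrayInd(lin, d)
  lev <- g[lin]
  pos_in <- integer(prod(d)); pos_in[lin] <- seq_along(lin)

  # neighbour lookup for one offset: index into `lin` of v+off, 0 if not in mask
  neighbour_of <- function(off) {
    nb <- sweep(ijk, 2, off, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    out <- integer(length(lin))
    out[ok] <- pos_in[nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
                      (nb[ok, 3] - 1L) * d[1] * d[2]]
    out
  }

  # ---- GLCM (per direction, symmetric) ----
  glcm_dir <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    nb <- neighbour_of(dirs[r, ])
    has <- nb > 0L
    a <- lev[has]; b <- lev[nb[has]]
    counts <- tabulate(c(a + (b - 1L) * L, b + (a - 1L) * L), L * L)
    glcm_dir[[r]] <- matrix(counts, L, L)
  }
  glcm <- Reduce(`+`, glcm_dir)

  # ---- NGLDM ----
  nbr_sum <- numeric(length(lin))
  nbr_cnt <- integer(length(lin))
  for (r in seq_len(nrow(dirs))) for (sgn in c(1L, -1L)) {
    nb <- neighbour_of(sgn * dirs[r, ])
    has <- nb > 0L
    nbr_sum[has] <- nbr_sum[has] + lev[nb[has]]
    nbr_cnt[has] <- nbr_cnt[has] + 1L
  }
  use <- nbr_cnt > 0L
  diffv <- abs(lev[use] - nbr_sum[use] / nbr_cnt[use])
  s <- vapply(seq_len(L), function(i) sum(diffv[lev[use] == i]), numeric(1))
  ncount <- tabulate(lev[use], L)

  # ---- GLRLM (remaining-run-length by backward sweep along each direction) ----
  glrlm <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    nxt <- neighbour_of(off)
    cont <- nxt > 0L
    cont[cont] <- lev[nxt[cont]] == lev[cont]
    prv <- neighbour_of(-off)
    is_start <- !(prv > 0L)
    is_start[!is_start] <- lev[prv[!is_start]] != lev[!is_start]
    # order so that each voxel's successor is processed before it
    ord <- order(ijk %*% off, decreasing = TRUE)
    rl <- integer(length(lin))
    for (v in ord) rl[v] <- if (cont[v]) rl[nxt[v]] + 1L else 1L
    st <- which(is_start)
    maxr <- max(rl[st])
    glrlm[[r]] <- matrix(tabulate(lev[st] + (rl[st] - 1L) * L, L * maxr),
                         L, maxr)
  }

  # ---- GLZLM ----
  lab <- label_components(mask, values = g)
  zl <- lab[mask]
  zsize <- tabulate(zl)
  zlevel <- lev[match(seq_along(zsize), zl)]
  glzlm <- matrix(tabulate(zlevel + (zsize - 1L) * L, L * max(zsize)),
                  L, max(zsize))

  structure(list(glcm = glcm, glcm_dir = glcm_dir,
                 ngldm = list(s = s, n = ncount),
                 glrlm = glrlm, glzlm = glzlm,
                 n_levels = L, n_voxels = n_vox),
            class = "texture_matrices")
}

# GLCM features from one (count) matrix
glcm_features_one <- function(M) {
  tot <- sum(M)
  p <- M / tot
  L <- nrow(p)
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu_i <- sum(seq_len(L) * pi_)
  var_i <- sum((seq_len(L) - mu_i)^2 * pi_)
  pn <- p[p > 0]
  corr <- if (var_i > 0)
    sum((i - mu_i) * (j - mu_i) * p) / var_i   # symmetric: mu_i = mu_j
  else NA_real_
  c(glcm_homogeneity = sum(p / (1 + abs(i - j))),
    glcm_energy = sum(p^2),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = corr,
    glcm_entropy = -sum(pn * log2(pn)),
    glcm_dissimilarity = sum(abs(i - j) * p))
}

# run/zone-length style features from one count matrix (rows = level,
# cols = length), given the number of voxels
rl_features_one <- function(M, n_vox, prefix, length_names) {
  Nr <- sum(M)
  i <- row(M); l <- col(M)
  p <- M / Nr
  f <- c(sum(p / l^2), sum(p * l^2), sum(p / i^2), sum(p * i^2),
         sum(p / (i^2 * l^2)), sum(p * i^2 / l^2), sum(p * l^2 / i^2),
         sum(p * i^2 * l^2),
         sum(rowSums(M)^2) / Nr, sum(colSums(M)^2) / Nr, Nr / n_vox)
  names(f) <- paste0(prefix, "_", length_names)
  f
}

#' Higher-order texture features
#'
#' Computes the 31 higher-order features from the four texture matrices:
#' 6 GLCM (homogeneity, energy, contrast, correlation, entropy in bits,
#' dissimilarity), 3 NGLDM (coarseness, contrast, busyness, in the
#' classical neighbourhood grey-tone difference formulation), 11 GLRLM and
#' 11 GLZLM (short/long-run or zone emphases, low/high grey-level
#' emphases and their four crosses, grey-level nonuniformity, run-length /
#' zone-length nonuniformity, and run / zone percentage).
#'
#' GLRLM features are computed per direction and averaged over the 13
#' directions. GLCM features use the merged (summed) directional matrix by
#' default; \code{glcm_aggregation = "average"} instead averages features
#' over per-direction matrices.
#'
#' For a single-level (constant) tumor, GLCM correlation is undefined and
#' returned as \code{NA}.
#'
#' @param mats a [build_texture_matrices()] result.
#' @param glcm_aggregation \code{"merged"} (default) or \code{"average"}.
#' @return Named numeric vector of exactly 31 features.
#' @export
higher_order_features <- function(mats,
                                  glcm_aggregation = c("merged", "average")) {
  stopifnot(inherits(mats, "texture_matrices"))
  glcm_aggregation <- match.arg(glcm_aggregation)

  glcm_f <- if (glcm_aggregation == "merged") {
    glcm_features_one(mats$glcm)
  } else {
    rowMeans(vapply(mats$glcm_dir, glcm_features_one, numeric(6)))
  }

  # NGLDM, classical formulation on the difference vector
  s <- mats$ngldm$s
  ncnt <- mats$ngldm$n
  N <- sum(ncnt)
  pi_ <- ncnt / N
  occ <- which(pi_ > 0)
  Ng <- length(occ)
  coarseness <- 1 / sum(pi_ * s)
  if (Ng > 1) {
    ii <- outer(occ, occ, function(a, b) (a - b)^2)
    pp <- outer(pi_[occ], pi_[occ])
    contrast <- sum(pp * ii) / (Ng * (Ng - 1)) * sum(s) / N
    busy_den <- sum(abs(outer(occ * pi_[occ], occ * pi_[occ], `-`)))
    busyness <- if (busy_den > 0) sum(pi_ * s) / busy_den else NA_real_
  } else {
    contrast <- 0
    busyness <- NA_real_
  }
  ngldm_f <- c(ngldm_coarseness = coarseness, ngldm_contrast = contrast,
               ngldm_busyness = busyness)

  run_names <- c("sre", "lre", "lgre", "hgre", "srlge", "srhge",
                 "lrlge", "lrhge", "glnu", "rlnu", "rp")
  glrlm_f <- rowMeans(vapply(mats$glrlm, rl_features_one,
                             numeric(11), n_vox = mats$n_voxels,
                             prefix = "glrlm", length_names = run_names))
  zone_names <- c("sze", "lze", "lgze", "hgze", "szlge", "szhge",
                  "lzlge", "lzhge", "glnu", "zlnu", "zp")
  glzlm_f <- rl_features_one(mats$glzlm, mats$n_voxels, "glzlm", zone_names)

  c(glcm_f, ngldm_f, glrlm_f, glzlm_f)
}
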