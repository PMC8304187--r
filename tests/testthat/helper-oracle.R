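# Brute-force enumeration oracles, deliberately written as explicit loops
# so they share no code path with the package implementation.

oracle_all_offsets_26 <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    if (!(dx == 0 && dy == 0 && dz == 0))
      out[[length(out) + 1L]] <- c(dx, dy, dz)
  out
}

# one offset per antipodal pair, same orientation convention as the package
oracle_offsets_13 <- function() {
  keep <- list()
  for (off in oracle_all_offsets_26()) {
    first_nonzero <- off[off != 0][1]
    if (first_nonzero > 0) keep[[length(keep) + 1L]] <- off
  }
  keep
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric merged co-occurrence counts over the 13 directions
oracle_glcm <- function(lev, L) {
  d <- dim(lev)
  M <- matrix(0, L, L)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    for (off in oracle_offsets_13()) {
      p <- c(i, j, k) + off
      if (!in_bounds(p, d)) next
      b <- lev[p[1], p[2], p[3]]
      if (is.na(b)) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  M
}

# neighbourhood grey-level difference vector: s (sum of |level - mean of
# in-mask 26-neighbours|) and n (voxel counts) per level
oracle_ngldm <- function(lev, L) {
  d <- dim(lev)
  s <- numeric(L)
  n <- integer(L)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    nbr <- c()
    for (off in oracle_all_offsets_26()) {
      p <- c(i, j, k) + off
      if (!in_bounds(p, d)) next
      b <- lev[p[1], p[2], p[3]]
      if (!is.na(b)) nbr <- c(nbr, b)
    }
    if (length(nbr) == 0) next
    s[a] <- s[a] + abs(a - mean(nbr))
    n[a] <- n[a] + 1L
  }
  list(s = s, n = n)
}

# run-length matrix for one direction: walk every maximal run explicitly
oracle_glrlm_dir <- function(lev, L, off) {
  d <- dim(lev)
  runs <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    prev <- c(i, j, k) - off
    if (in_bounds(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == a) next  # not a run start
    len <- 1L
    p <- c(i, j, k) + off
    while (in_bounds(p, d) && !is.na(lev[p[1], p[2], p[3]]) &&
           lev[p[1], p[2], p[3]] == a) {
      len <- len + 1L
      p <- p + off
    }
    runs[[length(runs) + 1L]] <- c(a, len)
  }
  maxr <- max(vapply(runs, `[`, integer(1), 2))
  M <- matrix(0, L, maxr)
  for (r in runs) M[r[1], r[2]] <- M[r[1], r[2]] + 1
  M
}

# zone-length matrix: flood-fill 26-connected equal-level zones
oracle_glzlm <- function(lev, L) {
  d <- dim(lev)
  visited <- array(FALSE, d)
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a) || visited[i, j, k]) next
    queue <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (off in oracle_all_offsets_26()) {
        p <- q + off
        if (!in_bounds(p, d) || visited[p[1], p[2], p[3]]) next
        b <- lev[p[1], p[2], p[3]]
        if (!is.na(b) && b == a) {
          visited[p[1], p[2], p[3]] <- TRUE
          queue[[length(queue) + 1L]] <- p
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(a, size)
  }
  maxz <- max(vapply(zones, `[`, integer(1), 2))
  M <- matrix(0, L, maxz)
  for (z in zones) M[z[1], z[2]] <- M[z[1], z[2]] + 1
  M
}

# feature formulas recomputed with explicit loops over matrix entries
oracle_glcm_features <- function(M) {
  p <- M / sum(M)
  L <- nrow(p)
  hom <- ener <- contr <- ent <- dis <- 0
  mu <- 0; varr <- 0
  for (i in 1:L) mu <- mu + i * sum(p[i, ])
  for (i in 1:L) varr <- varr + (i - mu)^2 * sum(p[i, ])
  num <- 0
  for (i in 1:L) for (j in 1:L) {
    hom <- hom + p[i, j] / (1 + abs(i - j))
    ener <- ener + p[i, j]^2
    contr <- contr + (i - j)^2 * p[i, j]
    dis <- dis + abs(i - j) * p[i, j]
    num <- num + (i - mu) * (j - mu) * p[i, j]
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  }
  corr <- if (varr > 0) num / varr else NA_real_
  c(glcm_homogeneity = hom, glcm_energy = ener, glcm_contrast = contr,
    glcm_correlation = corr, glcm_entropy = ent, glcm_dissimilarity = dis)
}

oracle_ngldm_features <- function(s, n) {
  N <- sum(n)
  p <- n / N
  occ <- which(p > 0)
  Ng <- length(occ)
  coars <- 1 / sum(p * s)
  if (Ng > 1) {
    acc <- 0
    for (i in occ) for (j in occ) acc <- acc + p[i] * p[j] * (i - j)^2
    contr <- acc / (Ng * (Ng - 1)) * sum(s) / N
    den <- 0
    for (i in occ) for (j in occ) den <- den + abs(i * p[i] - j * p[j])
    busy <- if (den > 0) sum(p * s) / den else NA_real_
  } else {
    contr <- 0
    busy <- NA_real_
  }
  c(ngldm_coarseness = coars, ngldm_contrast = contr, ngldm_busyness = busy)
}

oracle_rl_features <- function(M, n_vox) {
  Nr <- sum(M)
  L <- nrow(M); R <- ncol(M)
  f <- numeric(11)
  for (i in 1:L) for (l in 1:R) {
    q <- M[i, l] / Nr
    f[1] <- f[1] + q / l^2;        f[2] <- f[2] + q * l^2
    f[3] <- f[3] + q / i^2;        f[4] <- f[4] + q * i^2
    f[5] <- f[5] + q / (i^2 * l^2); f[6] <- f[6] + q * i^2 / l^2
    f[7] <- f[7] + q * l^2 / i^2;  f[8] <- f[8] + q * i^2 * l^2
  }
  for (i in 1:L) f[9] <- f[9] + sum(M[i, ])^2 / Nr
  for (l in 1:R) f[10] <- f[10] + sum(M[, l])^2 / Nr
  f[11] <- Nr / n_vox
  f
}

# full 31-feature vector from a discretized array, via the oracle matrices
oracle_higher_order <- function(lev, L, n_vox) {
  glcm <- oracle_glcm_features(oracle_glcm(lev, L))
  ng <- oracle_ngldm(lev, L)
  ngf <- oracle_ngldm_features(ng$s, ng$n)
  run <- rowMeans(vapply(oracle_offsets_13(), function(off)
    oracle_rl_features(oracle_glrlm_dir(lev, L, off), n_vox), numeric(11)))
  zone <- oracle_rl_features(oracle_glzlm(lev, L), n_vox)
  names(run) <- paste0("glrlm_", c("sre", "lre", "lgre", "hgre", "srlge",
                                   "srhge", "lrlge", "lrhge", "glnu",
                                   "rlnu", "rp"))
  names(zone) <- paste0("glzlm_", c("sze", "lze", "lgze", "hgze", "szlge",
                                    "szhge", "lzlge", "lzhge", "glnu",
                                    "zlnu", "zp"))
  c(glcm, ngf, run, zone)
}

# two-pass brute-force adaptive threshold
oracle_nestle <- function(suv, voi, bg) {
  d <- dim(suv)
  mx <- -Inf
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (voi[i, j, k] && suv[i, j, k] > mx) mx <- suv[i, j, k]
  hot <- c(); bgv <- c()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (voi[i, j, k] && suv[i, j, k] > 0.7 * mx) hot <- c(hot, suv[i, j, k])
    if (bg[i, j, k]) bgv <- c(bgv, suv[i, j, k])
  }
  thr <- 0.3 * mean(hot) + mean(bgv)
  tumor <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (voi[i, j, k] && suv[i, j, k] >= thr) tumor[i, j, k] <- TRUE
  list(threshold = thr, tumor = tumor)
}
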