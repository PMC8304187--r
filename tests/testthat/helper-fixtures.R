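# In-code fixtures shared across test files.

# a compact phantom spec that renders quickly (tumor ~200-300 voxels)
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(24L, 24L, 24L), spacing = c(4, 4, 4),
               tumor_center = c(48, 48, 48), tumor_radius_mm = 15.5,
               vertebra_centers = cbind(20, 20, seq(12, 84, by = 14.5)),
               vertebra_radius_mm = 5,
               liver_center = c(76, 76, 24), liver_radius_mm = 8,
               seed = seed, ...)
}

# random SUV volume + blob-like VOI for segmentation stress tests
random_voi_case <- function(seed, d = c(10L, 10L, 10L)) {
  set.seed(seed)
  arr <- array(stats::runif(prod(d), 0.2, 2), d)
  ctr <- stats::runif(3, 4, 7)
  r <- stats::runif(1, 2.2, 3.5)
  ijk <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  voi <- array(rowSums(sweep(ijk, 2, ctr, `-`)^2) <= r^2, d)
  arr[voi] <- arr[voi] + stats::runif(sum(voi), 2, 8)   # hot lesion
  vol <- suv_volume(arr, c(4, 4, 4))
  bg <- default_background_mask(vol, voi)
  list(volume = vol, voi = voi, bg = bg)
}

# a digitized ball mask of radius r voxels
ball_mask <- function(r, pad = 4L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- rep((n + 1) / 2, 3)
  ijk <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  array(rowSums(sweep(ijk, 2, ctr, `-`)^2) <= r^2, dim = c(n, n, n))
}

# exponential proportional-hazards cohort with a single binary covariate,
# used for recovery tests independent of the package's cohort generator
simple_ph_cohort <- function(n, beta, base_rate = 0.05, censor_rate = 0,
                             seed = 1L, x = NULL) {
  set.seed(seed)
  if (is.null(x)) x <- stats::rbinom(n, 1, 0.5)
  t_ev <- stats::rexp(n, rate = base_rate * exp(beta * x))
  if (censor_rate > 0) {
    t_c <- stats::rexp(n, rate = censor_rate)
    data.frame(x = x, time = pmin(t_ev, t_c),
               event = as.integer(t_ev <= t_c))
  } else {
    data.frame(x = x, time = t_ev, event = 1L)
  }
}
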