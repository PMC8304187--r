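#' Resample tumor SUV into relative grey levels
#'
#' Discretizes the SUV values of the masked tumor into \code{levels}
#' relative intensity bins between zero and the tumor maximum:
#' \deqn{g(v) = \min(L, \lfloor SUV(v) / SUV_{max} \cdot L \rfloor + 1)}
#' Bins are left-closed of width \code{max/L} over \code{[0, max]}; the
#' value 0 maps to level 1 and the maximum is clamped into the top bin.
#' Texture analysis uses 64 levels by default.
#'
#' @param volume an [suv_volume()].
#' @param tumor_mask logical mask (non-empty).
#' @param levels number of grey levels L (>= 2; default 64).
#' @return A list of class \code{discretized_voi}: \code{levels} (integer
#'   array, NA outside the mask), \code{mask}, \code{n_levels},
#'   \code{suv_max}, \code{spacing}.
#' @examples
#' arr <- array(seq(0.1, 10, length.out = 27), c(3, 3, 3))
#' d <- discretize(suv_volume(arr, c(4, 4, 4)), array(TRUE, c(3, 3, 3)))
#' range(d$levels)
#' @export
discretize <- function(volume, tumor_mask, levels = 64L) {
  stopifnot(inherits(volume, "suv_volume"))
  tumor_mask <- check_mask(tumor_mask, volume, "tumor_mask")
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("`levels` must be an integer >= 2")
  mx <- max(volume$data[tumor_mask])
  if (mx <= 0)
    stop("tumor maximum SUV is zero; relative binning over [0, max] is undefined")
  g <- array(NA_integer_, dim(volume$data))
  v <- volume$data[tumor_mask]
  g[tumor_mask] <- pmin(levels, as.integer(floor(v / mx * levels)) + 1L)
  structure(list(levels = g, mask = tumor_mask, n_levels = levels,
                 suv_max = mx, spacing = volume$spacing),
            class = "discretized_voi")
}

#' Conventional PET parameters of a segmented tumor
#'
#' \describe{
#'   \item{suv_max}{largest tumor voxel SUV.}
#'   \item{suv_peak}{mean SUV within a 1 cm\eqn{^3} sphere (radius about
#'     6.2 mm) centred on the hottest tumor voxel; every volume voxel whose
#'     centre falls inside the sphere contributes, whether or not it lies in
#'     the tumor mask (the sphere may spill over the lesion edge).}
#'   \item{mtv_cm3}{metabolic tumor volume: voxel count times voxel volume,
#'     cm\eqn{^3}.}
#'   \item{tlg_g}{total lesion glycolysis: MTV times mean tumor SUV, grams.}
#' }
#'
#' @param volume an [suv_volume()].
#' @param tumor_mask logical mask (non-empty).
#' @return Named numeric vector \code{c(suv_max, suv_peak, mtv_cm3, tlg_g)}.
#' @examples
#' arr <- array(5, c(5, 5, 4))
#' conventional_params(suv_volume(arr, c(4, 4, 4)), array(TRUE, dim(arr)))
#' @export
conventional_params <- function(volume, tumor_mask) {
  stopifnot(inherits(volume, "suv_volume"))
  tumor_mask <- check_mask(tumor_mask, volume, "tumor_mask")
  suv <- volume$data
  vals <- suv[tumor_mask]
  mx <- max(vals)
  mtv <- sum(tumor_mask) * voxel_volume_cm3(volume)
  tlg <- mtv * mean(vals)

  # peak: 1 cm^3 sphere centred on the hottest tumor voxel
  lin <- which(tumor_mask)
  hot <- lin[which.max(suv[lin])]
  d <- dim(suv)
  sp <- volume$spacing
  hot_ijk <- arrayInd(hot, d)
  center <- (hot_ijk - 0.5) * sp
  r <- (3 * 1000 / (4 * pi))^(1 / 3)   # radius of a 1 cm^3 sphere, mm
  # restrict to the bounding box around the hot voxel for speed
  lo <- pmax(1L, as.integer(floor((center - r) / sp + 0.5)))
  hi <- pmin(d, as.integer(ceiling((center + r) / sp + 0.5)))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  cx <- (ii - 0.5) * sp[1] - center[1]
  cy <- (jj - 0.5) * sp[2] - center[2]
  cz <- (kk - 0.5) * sp[3] - center[3]
  dist2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  inside <- dist2 <= r^2
  peak <- mean(suv[ii, jj, kk, drop = FALSE][inside])

  c(suv_max = mx, suv_peak = peak, mtv_cm3 = mtv, tlg_g = tlg)
}
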