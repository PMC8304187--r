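#' Adaptive-threshold tumor delineation (Nestle method)
#'
#' Delineates the tumor inside a manually drawn VOI using the
#' background-corrected adaptive threshold
#' \deqn{threshold = 0.3 \times \bar{S}_{hot} + \bar{S}_{bg}}
#' where \eqn{\bar{S}_{hot}} is the mean SUV of VOI voxels with uptake
#' strictly greater than 70\% of the VOI maximum, and \eqn{\bar{S}_{bg}} is
#' the mean SUV over the supplied background region. The tumor mask is every
#' VOI voxel with SUV greater than or equal to the threshold (ties at the
#' threshold are kept).
#'
#' @param volume an [suv_volume()].
#' @param manual_voi logical mask of the manually drawn VOI (non-empty).
#' @param background logical mask of background voxels, disjoint from the
#'   VOI; see [default_background_mask()] for the packaged convention.
#' @return A list of class \code{nestle_segmentation}: \code{threshold},
#'   \code{tumor_mask}, \code{n_voxels}, \code{hot_mean} (mean over
#'   voxels > 70\% of max), \code{background_mean}, \code{max_suv}.
#' @examples
#' arr <- array(0, c(8, 8, 8)); arr[3:6, 3:6, 3:6] <- 10
#' vol <- suv_volume(arr, c(4, 4, 4))
#' voi <- array(FALSE, dim(arr)); voi[2:7, 2:7, 2:7] <- TRUE
#' bg <- array(FALSE, dim(arr)); bg[1, , ] <- TRUE
#' nestle_threshold(vol, voi, bg)$threshold  # 0.3 * 10 + 0 = 3
#' @export
nestle_threshold <- function(volume, manual_voi, background) {
  stopifnot(inherits(volume, "suv_volume"))
  manual_voi <- check_mask(manual_voi, volume, "manual_voi")
  background <- check_mask(background, volume, "background")
  if (any(manual_voi & background))
    stop("background mask overlaps the manual VOI; they must be disjoint")
  suv <- volume$data
  voi_vals <- suv[manual_voi]
  mx <- max(voi_vals)
  hot <- voi_vals[voi_vals > 0.7 * mx]   # strict ">": max always qualifies
  hot_mean <- mean(hot)
  bg_mean <- mean(suv[background])
  thr <- 0.3 * hot_mean + bg_mean
  tumor <- manual_voi & suv >= thr
  if (!any(tumor))
    stop(sprintf(paste0("adaptive threshold %.4g exceeds the VOI maximum ",
                        "%.4g; no tumor voxels survive (background too hot ",
                        "relative to the lesion)"), thr, mx))
  structure(list(threshold = thr, tumor_mask = tumor,
                 n_voxels = sum(tumor), hot_mean = hot_mean,
                 background_mean = bg_mean, max_suv = mx),
            class = "nestle_segmentation")
}

#' @export
print.nestle_segmentation <- function(x, ...) {
  cat(sprintf("Adaptive-threshold segmentation: threshold %.4g SUV (0.3 x %.4g + %.4g), %d tumor voxels\n",
              x$threshold, x$hot_mean, x$background_mean, x$n_voxels))
  invisible(x)
}

#' Default background region for the adaptive threshold
#'
#' The background is a shell of configurable thickness around the manual
#' VOI, excluding any voxel whose SUV exceeds 70\% of the VOI maximum (so
#' spill-over of lesion uptake into the shell does not inflate the
#' background term). Callers can always supply their own mask instead.
#'
#' @param volume an [suv_volume()].
#' @param manual_voi logical VOI mask.
#' @param thickness shell thickness in voxels (default 2).
#' @param hot_fraction voxels above this fraction of the VOI max are dropped
#'   from the shell (default 0.7).
#' @return Logical background mask.
#' @export
default_background_mask <- function(volume, manual_voi, thickness = 2L,
                                    hot_fraction = 0.7) {
  manual_voi <- check_mask(manual_voi, volume, "manual_voi")
  shell <- dilate_mask(manual_voi, thickness) & !manual_voi
  mx <- max(volume$data[manual_voi])
  shell[volume$data > hot_fraction * mx] <- FALSE
  if (!any(shell))
    stop("background shell is empty; supply an explicit background mask")
  shell
}

#' Mean SUV within a fractional isocontour
#'
#' Returns the mean SUV over VOI voxels whose SUV is at least
#' \code{fraction} times the VOI maximum. Used with \code{fraction = 0.75}
#' for vertebral-body marrow uptake. The maximum voxel always qualifies, so
#' the result is defined for every non-empty VOI.
#'
#' @param volume an [suv_volume()].
#' @param voi logical mask (non-empty).
#' @param fraction cutoff as a proportion of the VOI maximum, in (0, 1].
#' @return Mean SUV within the isocontour (scalar).
#' @examples
#' arr <- array(c(2.0, 1.6, 1.4, 0), c(4, 1, 1))
#' vol <- suv_volume(arr, c(4, 4, 4))
#' voi <- array(c(TRUE, TRUE, TRUE, FALSE), dim(arr))
#' isocontour_mean(vol, voi, 0.75)  # mean(2.0, 1.6) = 1.8
#' @export
isocontour_mean <- function(volume, voi, fraction = 0.75) {
  stopifnot(inherits(volume, "suv_volume"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  voi <- check_mask(voi, volume, "voi")
  vals <- volume$data[voi]
  mean(vals[vals >= fraction * max(vals)])
}

#' Bone-marrow and liver uptake measurement
#'
#' Computes per-vertebra SUV as the 75\% isocontour mean within each
#' vertebral VOI, bone-marrow SUV (BM SUV) as the unweighted mean of the
#' per-vertebra values, liver SUV as the plain mean over the liver VOI (no
#' isocontour), and the bone marrow-to-liver ratio BLR = BM SUV / liver
#' mean. Up to six vertebral VOIs are accepted; fewer model the exclusion
#' of degenerate vertebrae (osteoarthritic change, fracture, surgery).
#'
#' @param volume an [suv_volume()].
#' @param vertebral_vois list of 1–6 logical masks.
#' @param liver_voi logical mask (non-empty).
#' @param fraction isocontour fraction for the vertebrae (default 0.75).
#' @return A list of class \code{marrow_measurement}:
#'   \code{vertebra_suv} (vector), \code{bm_suv}, \code{liver_suv},
#'   \code{blr}.
#' @export
measure_bone_marrow <- function(volume, vertebral_vois, liver_voi,
                                fraction = 0.75) {
  stopifnot(inherits(volume, "suv_volume"))
  if (!is.list(vertebral_vois) || length(vertebral_vois) < 1L)
    stop("at least one vertebral VOI is required")
  if (length(vertebral_vois) > 6L)
    stop("at most six vertebral VOIs are supported")
  per_vert <- vapply(vertebral_vois, function(m)
    isocontour_mean(volume, m, fraction), numeric(1))
  liver_voi <- check_mask(liver_voi, volume, "liver_voi")
  liver <- mean(volume$data[liver_voi])
  bm <- mean(per_vert)
  if (liver <= 0)
    stop("liver mean SUV is zero; BLR is undefined")
  structure(list(vertebra_suv = per_vert, bm_suv = bm,
                 liver_suv = liver, blr = bm / liver),
            class = "marrow_measurement")
}

#' @export
print.marrow_measurement <- function(x, ...) {
  cat(sprintf("Bone marrow: BM SUV %.3f over %d vertebrae, liver %.3f, BLR %.3f\n",
              x$bm_suv, length(x$vertebra_suv), x$liver_suv, x$blr))
  invisible(x)
}
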