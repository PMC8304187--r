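#' Specification of a synthetic PET phantom
#'
#' Describes a digital phantom emulating the measurement geometry of a
#' staging FDG PET scan in pancreatic cancer: one heterogeneous hot tumor on
#' a low-uptake background, six vertebral bodies for bone-marrow uptake
#' measurement, and a homogeneous liver reference region. All positions and
#' radii are physical (mm); intensities are SUV.
#'
#' Tumor heterogeneity is modelled as spatially correlated multiplicative
#' texture: a unit-variance Gaussian random field \code{G} with correlation
#' length \code{correlation_length_mm} is rank-transformed to a bounded
#' uniform field, and tumor voxels are set to
#' \code{mean_suv * (1 + h * (2 * pnorm(G) - 1))}, i.e. a multiplicative
#' factor uniform on \code{[1 - h, 1 + h]} with the field's spatial
#' structure. The relative intensity spread grows linearly with the
#' \code{heterogeneity} level \code{h}; at \code{h = 0} the tumor is
#' exactly homogeneous. Uncorrelated voxel noise would barely move
#' matrix-based texture features, which is why the field is spatially
#' correlated.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, mm per voxel.
#' @param tumor_center,tumor_radius_mm,tumor_mean_suv tumor sphere geometry
#'   (mm) and mean SUV.
#' @param heterogeneity dimensionless >= 0; multiplicative texture level.
#' @param correlation_length_mm correlation length of the tumor texture
#'   field (mm).
#' @param background_suv mean SUV of soft-tissue background.
#' @param vertebra_centers matrix (one row per vertebra, mm) of vertebral
#'   body centres; up to six.
#' @param vertebra_radius_mm radius of each vertebral sphere (mm).
#' @param vertebra_mean_suv per-vertebra mean SUV (recycled to the number of
#'   vertebrae). The default 1.74 is a typical cohort-median marrow SUV.
#' @param liver_center,liver_radius_mm,liver_mean_suv liver reference sphere.
#' @param noise_sd additive Gaussian noise standard deviation (SUV).
#' @param seed integer seed; one global seed fans out into fixed
#'   per-component substreams so that, e.g., switching noise on does not
#'   perturb the tumor texture field.
#' @return A \code{phantom_spec} list.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 72L),
                         spacing = c(4, 4, 4),
                         tumor_center = c(96, 128, 96),
                         tumor_radius_mm = 15.5,
                         tumor_mean_suv = 5,
                         heterogeneity = 0.5,
                         correlation_length_mm = 8,
                         background_suv = 0.5,
                         vertebra_centers = cbind(96, 64, seq(48, 228, by = 36)),
                         vertebra_radius_mm = 8,
                         vertebra_mean_suv = 1.74,
                         liver_center = c(40, 128, 180),
                         liver_radius_mm = 10,
                         liver_mean_suv = 2,
                         noise_sd = 0.05,
                         seed = 1L) {
  vertebra_centers <- matrix(as.numeric(vertebra_centers), ncol = 3)
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               tumor_center = as.numeric(tumor_center),
               tumor_radius_mm = tumor_radius_mm,
               tumor_mean_suv = tumor_mean_suv,
               heterogeneity = heterogeneity,
               correlation_length_mm = correlation_length_mm,
               background_suv = background_suv,
               vertebra_centers = vertebra_centers,
               vertebra_radius_mm = vertebra_radius_mm,
               vertebra_mean_suv = rep_len(vertebra_mean_suv, nrow(vertebra_centers)),
               liver_center = as.numeric(liver_center),
               liver_radius_mm = liver_radius_mm,
               liver_mean_suv = liver_mean_suv,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 2))
    stop("grid_shape must be three dimensions >= 2")
  if (any(spec$spacing <= 0)) stop("voxel spacing must be positive")
  means <- c(spec$tumor_mean_suv, spec$background_suv,
             spec$vertebra_mean_suv, spec$liver_mean_suv)
  if (any(means < 0)) stop("all mean SUVs must be >= 0")
  if (spec$heterogeneity < 0) stop("heterogeneity level must be >= 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (nrow(spec$vertebra_centers) < 1L || nrow(spec$vertebra_centers) > 6L)
    stop("between 1 and 6 vertebrae are supported")
  invisible(spec)
}

sphere_mask <- function(centers_mm, center, radius) {
  rowSums(sweep(centers_mm, 2, center, `-`)^2) <= radius^2
}

#' Generate a synthetic PET phantom
#'
#' Renders the phantom described by a [phantom_spec()]: a tumor sphere with
#' spatially correlated multiplicative heterogeneity, homogeneous vertebral
#' bodies and liver, a constant soft-tissue background, plus optional
#' additive Gaussian noise (clamped at zero, since SUV is non-negative).
#'
#' @param spec a [phantom_spec()].
#' @return A list of class \code{phantom} with elements
#'   \describe{
#'     \item{volume}{the rendered [suv_volume()].}
#'     \item{truth}{ground truth: \code{tumor_mask}, \code{vertebra_masks}
#'       (list), \code{liver_mask}, \code{prenoise} (the planted SUV volume
#'       before noise), \code{vertebra_mean_suv} (planted means).}
#'     \item{spec}{the spec used.}
#'   }
#' Identical spec + seed reproduce the volume bit-for-bit. Regions must be
#' pairwise disjoint and the rendered tumor must contain at least 64 voxels
#' (the eligibility floor used throughout the pipeline); violations are
#' errors naming the offending regions.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, heterogeneity = 0))
#' range(ph$volume$data[ph$truth$tumor_mask])  # exactly the tumor mean
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  vol0 <- suv_volume(array(spec$background_suv, d), spec$spacing)
  ctr <- voxel_centers(vol0)

  tumor <- array(sphere_mask(ctr, spec$tumor_center, spec$tumor_radius_mm), d)
  if (sum(tumor) < 64L)
    stop(sprintf(paste0("tumor renders to %d voxels (< 64) at this radius/",
                        "spacing; enlarge the tumor or refine the grid"),
                 sum(tumor)))
  verts <- lapply(seq_len(nrow(spec$vertebra_centers)), function(i)
    array(sphere_mask(ctr, spec$vertebra_centers[i, ], spec$vertebra_radius_mm), d))
  liver <- array(sphere_mask(ctr, spec$liver_center, spec$liver_radius_mm), d)

  regions <- c(list(tumor = tumor, liver = liver),
               stats::setNames(verts, paste0("vertebra_", seq_along(verts))))
  nm <- names(regions)
  for (i in seq_along(regions)) for (j in seq_len(i - 1L)) {
    if (any(regions[[i]] & regions[[j]]))
      stop(sprintf("regions '%s' and '%s' overlap; move or shrink them",
                   nm[j], nm[i]))
  }

  set.seed(spec$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4L)  # fixed substream layout

  arr <- array(spec$background_suv, d)
  for (i in seq_along(verts)) arr[verts[[i]]] <- spec$vertebra_mean_suv[i]
  arr[liver] <- spec$liver_mean_suv

  h <- spec$heterogeneity
  if (h > 0) {
    set.seed(sub[1])
    g <- array(stats::rnorm(prod(d)), d)
    g <- gaussian_smooth(g, spec$correlation_length_mm / (2 * spec$spacing))
    gt <- g[tumor]
    gt <- (gt - mean(gt)) / stats::sd(gt)
    # rank-transform the correlated Gaussian field to a bounded uniform
    # multiplicative field on [1-h, 1+h]: relative spread grows linearly
    # with h and there is no heavy tail or clipping atom, either of which
    # would distort relative (max-normalized) binning downstream
    arr[tumor] <- spec$tumor_mean_suv * (1 + h * (2 * stats::pnorm(gt) - 1))
  } else {
    arr[tumor] <- spec$tumor_mean_suv
  }
  prenoise <- arr

  if (spec$noise_sd > 0) {
    set.seed(sub[2])
    arr <- pmax(arr + stats::rnorm(prod(d), sd = spec$noise_sd), 0)
    arr <- array(arr, d)
  }

  structure(list(volume = suv_volume(arr, spec$spacing),
                 truth = list(tumor_mask = tumor, vertebra_masks = verts,
                              liver_mask = liver, prenoise = prenoise,
                              vertebra_mean_suv = spec$vertebra_mean_suv),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("PET phantom: tumor %d voxels, %d vertebrae, seed %d\n",
              sum(x$truth$tumor_mask), length(x$truth$vertebra_masks),
              x$spec$seed))
  invisible(x)
}

#' Write a phantom's volume and region masks to a directory
#'
#' One NIfTI file per region plus the volume itself
#' (\code{volume.nii.gz}, \code{tumor.nii.gz}, \code{vertebra_1.nii.gz}, ...,
#' \code{liver.nii.gz}).
#'
#' @param phantom a \code{phantom} from [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$volume, file.path(dir, "volume.nii.gz"))
  write_mask(phantom$truth$tumor_mask, phantom$volume,
             file.path(dir, "tumor.nii.gz"))
  for (i in seq_along(phantom$truth$vertebra_masks))
    write_mask(phantom$truth$vertebra_masks[[i]], phantom$volume,
               file.path(dir, sprintf("vertebra_%d.nii.gz", i)))
  write_mask(phantom$truth$liver_mask, phantom$volume,
             file.path(dir, "liver.nii.gz"))
  invisible(dir)
}
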