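#' SUV volume
#'
#' A 3D grid of standardized uptake values (SUV, dimensionless) with physical
#' voxel spacing. This is the raw imaging substrate every segmentation and
#' feature operation works on.
#'
#' @param data 3D numeric array of SUV values; all values must be >= 0.
#' @param spacing numeric length-3 vector, voxel edge length in mm per axis;
#'   all > 0.
#' @param origin numeric length-3 vector, physical offset of the first voxel
#'   centre in mm. Purely metadata; defaults to \code{spacing / 2}.
#' @return An object of class \code{suv_volume}: a list with elements
#'   \code{data}, \code{spacing}, \code{origin}.
#' @examples
#' v <- suv_volume(array(1, c(4, 4, 4)), spacing = c(4, 4, 4))
#' voxel_volume_cm3(v)
#' @export
suv_volume <- function(data, spacing, origin = spacing / 2) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (anyNA(data) || any(data < 0))
    stop("SUV values must be non-negative and non-missing")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive lengths (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("SUV volume: %d x %d x %d voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname suv_volume
#' @param volume an \code{suv_volume}.
#' @export
voxel_volume_cm3 <- function(volume) {
  stopifnot(inherits(volume, "suv_volume"))
  prod(volume$spacing) / 1000
}

#' Voxel centre coordinates (mm)
#'
#' @param volume an \code{suv_volume}.
#' @return n x 3 matrix of physical voxel-centre coordinates for all voxels,
#'   in array order.
#' @keywords internal
voxel_centers <- function(volume) {
  d <- dim(volume$data)
  sp <- volume$spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * sp[a])
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

# Check a logical mask against its volume; returns the mask coerced to logical.
check_mask <- function(mask, volume, name = "mask", allow_empty = FALSE) {
  if (inherits(mask, "suv_volume")) mask <- mask$data
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop(sprintf("`%s` must be a 3D array", name))
  if (!identical(dim(mask), dim(volume$data)))
    stop(sprintf("`%s` shape %s does not match volume shape %s", name,
                 paste(dim(mask), collapse = "x"),
                 paste(dim(volume$data), collapse = "x")))
  mask <- mask != 0
  if (!allow_empty && !any(mask))
    stop(sprintf("`%s` is empty", name))
  mask
}

#' Read / write SUV volumes and masks as NIfTI
#'
#' Volumes are stored in the NIfTI-1 convention with the voxel spacing in the
#' pixdim header fields. Masks are written as 0/1 volumes.
#'
#' @param volume an \code{suv_volume} (or, for \code{write_mask}, a logical
#'   array plus the volume that defines its grid).
#' @param path file path, conventionally ending in \code{.nii.gz}.
#' @return \code{read_volume} returns an \code{suv_volume};
#'   \code{read_mask} a logical array; the writers return \code{path}
#'   invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  img <- RNifti::asNifti(volume$data, reference = NULL)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  suv_volume(array(as.numeric(img), dim = dim(img)[1:3]),
             spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume
#' @param mask logical 3D array aligned to \code{volume}.
#' @export
write_mask <- function(mask, volume, path) {
  mask <- check_mask(mask, volume, allow_empty = TRUE)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img)[1:3])
}
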