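#' Names of the 41 imaging parameters
#'
#' The fixed inventory of the feature vector: 4 conventional parameters,
#' 6 first-order (histogram + shape) features, and 31 higher-order texture
#' features (6 GLCM, 3 NGLDM, 11 GLRLM, 11 GLZLM).
#'
#' @return A list with components \code{conventional}, \code{first_order},
#'   \code{higher_order} and \code{all} (character vectors; \code{all} has
#'   exactly 41 names).
#' @export
feature_names <- function() {
  conventional <- c("suv_max", "suv_peak", "mtv_cm3", "tlg_g")
  first_order <- c("firstorder_skewness", "firstorder_kurtosis",
                   "firstorder_entropy", "firstorder_energy",
                   "shape_sphericity", "shape_compacity")
  higher <- c(paste0("glcm_", c("homogeneity", "energy", "contrast",
                                "correlation", "entropy", "dissimilarity")),
              paste0("ngldm_", c("coarseness", "contrast", "busyness")),
              paste0("glrlm_", c("sre", "lre", "lgre", "hgre", "srlge",
                                 "srhge", "lrlge", "lrhge", "glnu", "rlnu",
                                 "rp")),
              paste0("glzlm_", c("sze", "lze", "lgze", "hgze", "szlge",
                                 "szhge", "lzlge", "lzhge", "glnu", "zlnu",
                                 "zp")))
  list(conventional = conventional, first_order = first_order,
       higher_order = higher, all = c(conventional, first_order, higher))
}

#' Extract the full 41-parameter feature vector of a tumor
#'
#' Runs the complete radiomic pipeline on a segmented tumor: conventional
#' parameters on the raw SUV, 64-level relative resampling, first-order
#' histogram/shape features, texture-matrix construction, and the 31
#' higher-order features. Tumors smaller than 64 voxels are rejected
#' (the eligibility floor below which texture analysis is unreliable).
#'
#' @param volume an [suv_volume()].
#' @param tumor_mask logical tumor mask with at least 64 voxels.
#' @param levels grey levels for resampling (default 64).
#' @param glcm_aggregation passed to [higher_order_features()].
#' @return Named numeric vector of exactly 41 features, in
#'   \code{feature_names()$all} order. Degenerate features (e.g. GLCM
#'   correlation of a constant tumor) are \code{NA}, never silently zero.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 3))
#' fv <- extract_all(ph$volume, ph$truth$tumor_mask)
#' length(fv)  # 41
#' @export
extract_all <- function(volume, tumor_mask, levels = 64L,
                        glcm_aggregation = "merged") {
  stopifnot(inherits(volume, "suv_volume"))
  tumor_mask <- check_mask(tumor_mask, volume, "tumor_mask")
  n <- sum(tumor_mask)
  if (n < 64L)
    stop(sprintf(paste0("tumor has %d voxels; tumors below 64 voxels are ",
                        "ineligible for radiomic analysis"), n))
  conv <- conventional_params(volume, tumor_mask)
  disc <- discretize(volume, tumor_mask, levels)
  fo <- first_order_features(disc)
  mats <- build_texture_matrices(disc)
  ho <- higher_order_features(mats, glcm_aggregation)
  out <- c(conv, fo, ho)
  stopifnot(identical(names(out), feature_names()$all))
  out
}

#' Extract features for a batch of tumors
#'
#' @param volumes list of [suv_volume()]s.
#' @param masks list of tumor masks, parallel to \code{volumes}.
#' @param ids character patient ids (defaults to sequence numbers).
#' @param ... passed to [extract_all()].
#' @return A \code{data.frame}: one row per tumor, \code{id} plus the 41
#'   feature columns.
#' @export
extract_features_table <- function(volumes, masks, ids = NULL, ...) {
  stopifnot(length(volumes) == length(masks))
  if (is.null(ids)) ids <- sprintf("T%03d", seq_along(volumes))
  rows <- mapply(function(v, m) extract_all(v, m, ...),
                 volumes, masks, SIMPLIFY = FALSE)
  out <- as.data.frame(do.call(rbind, rows))
  cbind(id = ids, out, stringsAsFactors = FALSE)
}
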