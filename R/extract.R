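#' Extract the full radiomic feature panel from one VOI
#'
#' Runs the configured preprocessing chain (optional resampling, optional
#' intensity re-segmentation, gray-level discretization) and computes the
#' enabled feature families. With all seven families enabled the result is
#' the standard 105-feature panel: 18 first order + 14 shape + 22 GLCM +
#' 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM. Family-level degeneracies yield
#' `NaN` values with a logged reason, never missing rows.
#'
#' @param vol an [image_volume()]
#' @param mask a [binary_mask()] congruent with `vol`
#' @param cfg an [extraction_config()]
#' @return data.frame with columns `family`, `name`, `ibsi_code`, `value`,
#'   `config_fingerprint`; one row per feature
#' @export
extract_all <- function(vol, mask, cfg = extraction_config()) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "binary_mask"))
  if (sum(mask$bits) == 0L) stop("cannot extract features from an empty mask")
  pp <- preprocess_region(vol, mask, cfg)
  d <- pp$region
  fams <- list(
    firstorder = function() firstorder_features(d),
    shape      = function() shape_features(pp$mask),
    glcm       = function() glcm_features(d),
    glrlm      = function() glrlm_features(d),
    glszm      = function() glszm_features(d),
    gldm       = function() gldm_features(d),
    ngtdm      = function() ngtdm_features(d))
  out <- do.call(rbind, lapply(cfg$enabled_families, function(f) fams[[f]]()))
  rownames(out) <- NULL
  out$ibsi_code <- map_features(paste(out$family, out$name))$code
  out$config_fingerprint <- config_fingerprint(cfg)
  out
}
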