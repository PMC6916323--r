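#' Extraction configuration
#'
#' Settings controlling preprocessing and feature extraction. Exactly one of
#' `bin_width` / `bin_count` is active. The defaults mirror a plain "basic"
#' extraction: no resampling, no re-segmentation, fixed bin width 25, all
#' seven feature families enabled. Every active setting is carried into the
#' output graph as provenance so nothing about a run is implicit.
#'
#' @param bin_width fixed bin width in intensity units (default 25)
#' @param bin_count fixed bin count alternative (disables `bin_width`)
#' @param resample_spacing optional mm triplet `(slice, row, col)` for grid
#'   resampling (trilinear image / nearest-neighbor mask)
#' @param reseg_range optional `[lo, hi]` intensity re-segmentation window
#' @param enabled_families subset of
#'   `c("firstorder","shape","glcm","glrlm","glszm","gldm","ngtdm")`
#' @param software_name,software_version,software_language provenance fields
#' @return an object of class `extraction_config`
#' @export
extraction_config <- function(bin_width = 25, bin_count = NULL,
                              resample_spacing = NULL, reseg_range = NULL,
                              enabled_families = FEATURE_FAMILIES,
                              software_name = "radsem",
                              software_version = as.character(
                                utils::packageVersion("radsem")),
                              software_language = "R") {
  if (!is.null(bin_count)) bin_width <- NULL
  if (is.null(bin_width) && is.null(bin_count))
    stop("one of bin_width / bin_count must be set")
  if (!is.null(bin_width) && bin_width <= 0) stop("bin_width must be > 0")
  if (!is.null(bin_count) && bin_count < 1) stop("bin_count must be >= 1")
  enabled_families <- match.arg(enabled_families, FEATURE_FAMILIES,
                                several.ok = TRUE)
  structure(list(bin_width = bin_width, bin_count = bin_count,
                 resample_spacing = resample_spacing,
                 reseg_range = reseg_range,
                 enabled_families = enabled_families,
                 software_name = software_name,
                 software_version = software_version,
                 software_language = software_language),
            class = "extraction_config")
}

#' The seven radiomic feature families
#'
#' Family names in panel order: first order statistics, 3-D shape, and the
#' five gray-level texture-matrix families.
#'
#' @format character vector of length 7
#' @export
FEATURE_FAMILIES <- c("firstorder", "shape", "glcm", "glrlm", "glszm",
                      "gldm", "ngtdm")

#' Load an extraction configuration from a YAML file
#'
#' Recognized keys are the arguments of [extraction_config()].
#'
#' @param path YAML file
#' @return an `extraction_config`
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(extraction_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(extraction_config, y)
}

#' Stable fingerprint of a configuration
#'
#' Used to stamp feature results and to build run-unique IRIs, so two runs
#' with different settings or software can never collide in a merged graph.
#'
#' @param cfg an [extraction_config()]
#' @return hexadecimal string
#' @export
config_fingerprint <- function(cfg) {
  s <- paste(
    "bw", cfg$bin_width %||% "-", "bc", cfg$bin_count %||% "-",
    "rs", paste(cfg$resample_spacing %||% "-", collapse = ","),
    "rg", paste(cfg$reseg_range %||% "-", collapse = ","),
    "fam", paste(sort(cfg$enabled_families), collapse = ","),
    "sw", cfg$software_name, cfg$software_version, cfg$software_language)
  sprintf("%08x", str_hash(s))
}

#' Intensity re-segmentation
#'
#' Removes voxels whose intensity falls outside `[lo, hi]` from the mask.
#'
#' @param vol an [image_volume()]
#' @param m a [binary_mask()] congruent with `vol`
#' @param range numeric `c(lo, hi)`; infinities allowed
#' @return the trimmed [binary_mask()]
#' @export
resegment <- function(vol, m, range) {
  stopifnot(length(range) == 2L, range[1] <= range[2])
  keep <- m$bits & vol$voxels >= range[1] & vol$voxels <= range[2]
  if (sum(keep) == 0L && sum(m$bits) > 0L)
    rs_log("warning", "re-segmentation removed every voxel of ROI '",
           m$roi_name, "'")
  m$bits <- keep
  m
}

.interp_axis_weights <- function(n_old, old_sp, new_sp) {
  n_new <- max(1L, as.integer(floor((n_old - 1L) * old_sp / new_sp)) + 1L)
  pos <- (seq_len(n_new) - 1L) * new_sp / old_sp  # in old index units
  lo <- pmin(floor(pos), n_old - 1L)
  hi <- pmin(lo + 1L, n_old - 1L)
  w <- pos - lo
  list(n = n_new, lo = lo + 1L, hi = hi + 1L, w = w)
}

#' Resample volume and mask to a new grid spacing
#'
#' Trilinear interpolation for the image, nearest neighbor for the mask. The
#' new grid keeps the first-voxel-center (origin) alignment; its extent covers
#' the old grid.
#'
#' @inheritParams resegment
#' @param new_spacing mm triplet `(slice, row, col)`, all > 0
#' @return list with resampled `vol` and `mask`
#' @export
resample <- function(vol, m, new_spacing) {
  stopifnot(length(new_spacing) == 3L, all(new_spacing > 0))
  dims <- dim(vol$voxels)
  ax <- lapply(1:3, function(a)
    .interp_axis_weights(dims[a], vol$spacing[a], new_spacing[a]))
  if (any(vapply(ax, `[[`, integer(1), "n") < 1L))
    stop("resampled grid would be empty")
  nk <- ax[[1]]$n; nr <- ax[[2]]$n; nc <- ax[[3]]$n

  lin <- function(arr, a) {
    # linear interpolation along axis `a` at index pairs lo/hi, weight w
    g <- function(i) switch(a,
      arr[i, , , drop = FALSE], arr[, i, , drop = FALSE],
      arr[, , i, drop = FALSE])
    lo <- g(ax[[a]]$lo)
    lo + sweep(g(ax[[a]]$hi) - lo, a, ax[[a]]$w, "*")
  }
  v <- vol$voxels
  v <- lin(v, 1); v <- lin(v, 2); v <- lin(v, 3)

  nn_idx <- function(a) {
    i <- round((seq_len(ax[[a]]$n) - 1L) * new_spacing[a] / vol$spacing[a]) + 1L
    pmin(pmax(i, 1L), dims[a])
  }
  mask_new <- m$bits[nn_idx(1), nn_idx(2), nn_idx(3), drop = FALSE]

  vol_new <- vol
  vol_new$voxels <- v
  vol_new$spacing <- as.numeric(new_spacing)
  m_new <- binary_mask(mask_new, m$roi_name, vol$origin,
                       as.numeric(new_spacing), vol$direction)
  list(vol = vol_new, mask = m_new)
}

.new_discretized <- function(levels_grid, mask, vol) {
  lv <- levels_grid[mask]
  structure(list(
    levels = as.integer(lv),
    grid = levels_grid,          # integer array, NA outside the mask
    mask = mask,
    ng = max(lv),
    raw = vol$voxels[mask],
    voxel_volume = prod(vol$spacing),
    spacing = vol$spacing),
    class = "discretized_region")
}

#' Fixed-bin-width gray-level discretization
#'
#' `level(x) = floor((x - min) / w) + 1` over masked voxels; bins anchor at
#' the region minimum. `Ng = floor((max - min)/w) + 1`.
#'
#' @inheritParams resegment
#' @param w bin width in intensity units (> 0)
#' @return a `discretized_region` carrying levels on the grid, `ng`, raw
#'   masked intensities and the voxel volume in mm^3
#' @export
discretize_fbw <- function(vol, m, w) {
  stopifnot(w > 0)
  if (sum(m$bits) == 0L) stop("cannot discretize an empty mask")
  x <- vol$voxels
  mn <- min(x[m$bits])
  g <- array(NA_integer_, dim = dim(x))
  g[m$bits] <- as.integer(floor((x[m$bits] - mn) / w)) + 1L
  .new_discretized(g, m$bits, vol)
}

#' Fixed-bin-count gray-level discretization
#'
#' `level(x) = min(n, floor(n (x - min) / (max - min)) + 1)`; a constant
#' region maps to level 1.
#'
#' @inheritParams resegment
#' @param n number of bins (>= 1)
#' @return a `discretized_region`
#' @export
discretize_fbc <- function(vol, m, n) {
  stopifnot(n >= 1)
  if (sum(m$bits) == 0L) stop("cannot discretize an empty mask")
  x <- vol$voxels
  vals <- x[m$bits]
  mn <- min(vals); mx <- max(vals)
  g <- array(NA_integer_, dim = dim(x))
  if (mx == mn) {
    g[m$bits] <- 1L
  } else {
    g[m$bits] <- pmin.int(as.integer(n),
                          as.integer(floor(n * (vals - mn) / (mx - mn))) + 1L)
  }
  .new_discretized(g, m$bits, vol)
}

# apply the configured preprocessing chain; returns list(vol, mask, region)
preprocess_region <- function(vol, mask, cfg) {
  if (!is.null(cfg$resample_spacing)) {
    rs <- resample(vol, mask, cfg$resample_spacing)
    vol <- rs$vol; mask <- rs$mask
  }
  if (!is.null(cfg$reseg_range)) mask <- resegment(vol, mask, cfg$reseg_range)
  region <- if (!is.null(cfg$bin_count))
    discretize_fbc(vol, mask, cfg$bin_count)
  else discretize_fbw(vol, mask, cfg$bin_width)
  list(vol = vol, mask = mask, region = region)
}
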