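#' Synthetic DICOM phantom cases
#'
#' The phantom generator writes valid DICOM image series (CT/PT/MR image
#' storage) plus an RT Structure Set with analytically known geometry and
#' intensities, so every downstream stage — series reading, contour
#' rasterization, preprocessing, feature extraction, semantic export — can be
#' exercised without any clinical data.
#'
#' Conventions: voxel indices are 0-based `(slice, row, col)`; the patient
#' coordinate system is LPS; a voxel center sits at
#' `origin + D %*% (spacing * index)` where the direction matrix `D` has unit
#' columns for the slice, row and column axes. Intensities are integers so
#' that 16-bit storage with rescale slope/intercept is exact.
#'
#' @param grid_shape voxels per axis, `(slices, rows, cols)`, each >= 1
#' @param spacing mm per axis `(between-slice, row, col)`, each > 0
#' @param origin patient-space mm coordinate of the first voxel center
#' @param intensity intensity pattern; see [intensity_constant()] and friends
#' @param rois list of ROI specifications from [roi_spec()]
#' @param patient_id patient identifier stamped into every file
#' @param modality one of `"CT"`, `"PT"`, `"MR"`
#' @param orientation `"identity"` for axis-aligned direction cosines, or
#'   `"rotated"` for a 30-degree in-plane rotation exercising the geometry code
#' @param seed integer seed for any randomized pattern and for UID derivation
#' @return an object of class `phantom_spec`
#' @examples
#' spec <- phantom_spec(grid_shape = c(4, 8, 8), intensity = intensity_constant(7))
#' dir <- tempfile(); case <- make_case(spec, dir)
#' vol <- read_series(case$series_dir)
#' stopifnot(all(vol$voxels == 7))
#' @export
phantom_spec <- function(grid_shape = c(8L, 16L, 16L),
                         spacing = c(2, 1, 1),
                         origin = c(0, 0, 0),
                         intensity = intensity_constant(0),
                         rois = list(),
                         patient_id = "PHANTOM-001",
                         modality = c("CT", "PT", "MR"),
                         orientation = c("identity", "rotated"),
                         seed = 20190101L) {
  modality <- match.arg(modality)
  orientation <- match.arg(orientation)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L)
  if (identical(intensity$kind, "sphere_lesion")) {
    ctr <- intensity$center; r <- intensity$radius
    stopifnot(r > 0)
    ext_lo <- origin - 0.5 * spacing[c(3, 2, 1)]
    ext_hi <- origin + (rev(grid_shape) - 0.5) * spacing[c(3, 2, 1)]
    if (identical(orientation, "identity") &&
        (any(ctr - r < ext_lo) || any(ctr + r > ext_hi)))
      stop("sphere lesion extends outside the phantom grid")
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), intensity = intensity,
                 rois = rois, patient_id = patient_id, modality = modality,
                 orientation = orientation, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param value constant intensity value (integer)
#' @export
intensity_constant <- function(value) {
  list(kind = "constant", value = as.integer(value))
}

#' @rdname phantom_spec
#' @param intercept,coef integer affine coefficients: voxel `(k, r, c)` takes
#'   value `intercept + coef[1]*k + coef[2]*r + coef[3]*c`
#' @export
intensity_axis_gradient <- function(intercept = 0L, coef = c(10L, 2L, 1L)) {
  list(kind = "axis_gradient", intercept = as.integer(intercept),
       coef = as.integer(coef))
}

#' @rdname phantom_spec
#' @param n_levels number of equally spaced gray levels to sample uniformly
#' @param step intensity distance between adjacent levels
#' @export
intensity_uniform_levels <- function(n_levels, step = 25L) {
  stopifnot(n_levels >= 1L)
  list(kind = "uniform_levels", n_levels = as.integer(n_levels),
       step = as.integer(step))
}

#' @rdname phantom_spec
#' @param center patient-space mm center of the spherical lesion
#' @param radius lesion radius in mm (> 0)
#' @param fg,bg foreground/background intensity (integers)
#' @export
intensity_sphere_lesion <- function(center, radius, fg = 100L, bg = -50L) {
  stopifnot(length(center) == 3L, radius > 0)
  list(kind = "sphere_lesion", center = as.numeric(center),
       radius = as.numeric(radius), fg = as.integer(fg), bg = as.integer(bg))
}

#' Planar ROI specification for the phantom structure set
#'
#' Shapes are drawn in-plane: coordinates `(u, v)` in mm are measured along the
#' column and row axes of the slice, relative to the slice's first voxel
#' center. For the default identity orientation these coincide with patient
#' `(x, y)` offsets from the volume origin.
#'
#' @param name ROI name written into the structure set
#' @param shape one of [shape_rectangle()], [shape_circle()], [shape_ring()]
#' @param slice_range 0-based slice indices carrying contours
#' @return an object of class `roi_spec`
#' @export
roi_spec <- function(name, shape, slice_range) {
  structure(list(name = name, shape = shape,
                 slice_range = as.integer(slice_range)),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @param center in-plane `(u, v)` mm center
#' @param extents full widths `(du, dv)` in mm
#' @export
shape_rectangle <- function(center, extents) {
  stopifnot(length(center) == 2L, length(extents) == 2L, all(extents > 0))
  list(kind = "rectangle", center = as.numeric(center),
       extents = as.numeric(extents))
}

#' @rdname roi_spec
#' @param radius circle radius in mm
#' @param n_vertices number of polygon vertices approximating the circle (>= 3)
#' @export
shape_circle <- function(center, radius, n_vertices = 64L) {
  stopifnot(length(center) == 2L, radius > 0, n_vertices >= 3L)
  list(kind = "circle", center = as.numeric(center), radius = as.numeric(radius),
       n_vertices = as.integer(n_vertices))
}

#' @rdname roi_spec
#' @param outer,inner two simple shapes (rectangle or circle); the inner one
#'   must lie strictly inside the outer one and cuts a hole via the even-odd rule
#' @export
shape_ring <- function(outer, inner) {
  stopifnot(outer$kind %in% c("rectangle", "circle"),
            inner$kind %in% c("rectangle", "circle"))
  list(kind = "ring", outer = outer, inner = inner)
}

# direction matrix: columns are unit vectors for (slice, row, col) axes
phantom_direction <- function(spec) {
  if (identical(spec$orientation, "rotated")) {
    th <- 30 * pi / 180
    d_col <- c(cos(th), sin(th), 0)
    d_row <- c(-sin(th), cos(th), 0)
  } else {
    d_col <- c(1, 0, 0)
    d_row <- c(0, 1, 0)
  }
  d_slice <- c(d_col[2] * d_row[3] - d_col[3] * d_row[2],
               d_col[3] * d_row[1] - d_col[1] * d_row[3],
               d_col[1] * d_row[2] - d_col[2] * d_row[1])
  cbind(slice = d_slice, row = d_row, col = d_col)
}

#' Evaluate the phantom's analytic intensity pattern
#'
#' Returns the exact voxel array the written series encodes — the reference for
#' read-back tests.
#'
#' @param spec a [phantom_spec()]
#' @return integer array of shape `grid_shape` (slice, row, col)
#' @export
phantom_volume <- function(spec) {
  dims <- spec$grid_shape
  pat <- spec$intensity
  if (pat$kind == "constant") {
    v <- array(pat$value, dim = dims)
  } else if (pat$kind == "axis_gradient") {
    k <- slice.index(array(0L, dims), 1) - 1L
    r <- slice.index(array(0L, dims), 2) - 1L
    cc <- slice.index(array(0L, dims), 3) - 1L
    v <- pat$intercept + pat$coef[1] * k + pat$coef[2] * r + pat$coef[3] * cc
  } else if (pat$kind == "uniform_levels") {
    n <- prod(dims)
    v <- withr_seed(spec$seed, {
      array(pat$step * (sample.int(pat$n_levels, n, replace = TRUE) - 1L),
            dim = dims)
    })
  } else if (pat$kind == "sphere_lesion") {
    ctr <- voxel_centers(dims, spec$spacing, spec$origin, phantom_direction(spec))
    d2 <- (ctr[, 1] - pat$center[1])^2 + (ctr[, 2] - pat$center[2])^2 +
      (ctr[, 3] - pat$center[3])^2
    v <- array(ifelse(d2 <= pat$radius^2, pat$fg, pat$bg), dim = dims)
  } else stop("unknown intensity pattern: ", pat$kind)
  storage.mode(v) <- "integer"
  v
}

# run expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# all voxel centers in patient mm, rows ordered (k,r,c) with c fastest? No:
# returned as matrix n x 3 aligned with array element order (k fastest per R
# column-major over dims (k,r,c))
voxel_centers <- function(dims, spacing, origin, direction) {
  k <- as.vector(slice.index(array(0L, dims), 1)) - 1L
  r <- as.vector(slice.index(array(0L, dims), 2)) - 1L
  cc <- as.vector(slice.index(array(0L, dims), 3)) - 1L
  idx <- cbind(k * spacing[1], r * spacing[2], cc * spacing[3])
  sweep(idx %*% t(direction), 2, origin, "+")
}

# per-slice polygon vertex lists for one ROI, in patient mm
# returns list over slice_range; each element a list of M x 3 matrices
roi_polygons <- function(spec, roi) {
  D <- phantom_direction(spec)
  poly2d <- function(shape) {
    if (shape$kind == "rectangle") {
      cu <- shape$center[1]; cv <- shape$center[2]
      du <- shape$extents[1] / 2; dv <- shape$extents[2] / 2
      cbind(u = c(cu - du, cu + du, cu + du, cu - du),
            v = c(cv - dv, cv - dv, cv + dv, cv + dv))
    } else if (shape$kind == "circle") {
      a <- 2 * pi * (seq_len(shape$n_vertices) - 1L) / shape$n_vertices
      cbind(u = shape$center[1] + shape$radius * cos(a),
            v = shape$center[2] + shape$radius * sin(a))
    } else stop("unknown shape kind: ", shape$kind)
  }
  shapes <- if (roi$shape$kind == "ring") list(roi$shape$outer, roi$shape$inner)
            else list(roi$shape)
  lapply(roi$slice_range, function(k) {
    slice_origin <- spec$origin + k * spec$spacing[1] * D[, "slice"]
    lapply(shapes, function(sh) {
      uv <- poly2d(sh)
      pts <- slice_origin +
        t(uv[, 1] %o% D[, "col"] + uv[, 2] %o% D[, "row"])
      t(pts)
    })
  })
}

.common_elems <- function(spec, uids, sop_class, sop_uid) {
  list(
    el(0x0008, 0x0016, "UI", sop_class),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0020, "DA", "20190101"),
    el(0x0008, 0x0030, "TM", "000000"),
    el(0x0010, 0x0010, "PN", spec$patient_id),
    el(0x0010, 0x0020, "LO", spec$patient_id),
    el(0x0020, 0x000D, "UI", uids$study),
    el(0x0020, 0x0010, "SH", "1")
  )
}

phantom_uids <- function(spec) {
  mk <- uid_factory(spec$patient_id, spec$seed)
  n_slices <- spec$grid_shape[1]
  list(study = mk(), series = mk(), frame_of_reference = mk(),
       rtstruct = mk(), sop = vapply(seq_len(n_slices), function(i) mk(),
                                     character(1)))
}

#' Write the phantom image series as DICOM Part-10 files
#'
#' One file per slice, sharing SeriesInstanceUID, FrameOfReferenceUID,
#' ImageOrientationPatient and PixelSpacing, with per-slice
#' ImagePositionPatient, such that reading the series back yields exactly the
#' analytic intensities of [phantom_volume()].
#'
#' @param spec a [phantom_spec()]
#' @param out_dir directory to write into (created if absent)
#' @return character vector of written file paths, invisibly
#' @export
write_phantom_series <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create series directory: ", out_dir)
  dims <- spec$grid_shape
  vox <- phantom_volume(spec)
  D <- phantom_direction(spec)
  uids <- phantom_uids(spec)
  intercept <- if (spec$modality == "CT") -1024 else 0
  stored <- vox - intercept
  if (min(stored) < -32768 || max(stored) > 32767)
    stop("phantom intensities exceed 16-bit storage range")
  iop <- c(D[, "col"], D[, "row"])
  sop_class <- SOP_CLASS[[spec$modality]]
  paths <- character(dims[1])
  for (k in seq_len(dims[1])) {
    ipp <- spec$origin + (k - 1L) * spec$spacing[1] * D[, "slice"]
    pix <- as.integer(t(stored[k, , , drop = TRUE]))  # row-major for DICOM
    ds <- c(.common_elems(spec, uids, sop_class, uids$sop[k]), list(
      el(0x0008, 0x0060, "CS", spec$modality),
      el(0x0020, 0x000E, "UI", uids$series),
      el(0x0020, 0x0011, "IS", 1L),
      el(0x0020, 0x0013, "IS", k),
      el(0x0020, 0x0032, "DS", ipp),
      el(0x0020, 0x0037, "DS", iop),
      el(0x0020, 0x0052, "UI", uids$frame_of_reference),
      el(0x0018, 0x0050, "DS", spec$spacing[1]),
      el(0x0028, 0x0002, "US", 1L),
      el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      el(0x0028, 0x0010, "US", dims[2]),
      el(0x0028, 0x0011, "US", dims[3]),
      el(0x0028, 0x0030, "DS", spec$spacing[c(2, 3)]),
      el(0x0028, 0x0100, "US", 16L),
      el(0x0028, 0x0101, "US", 16L),
      el(0x0028, 0x0102, "US", 15L),
      el(0x0028, 0x0103, "US", 1L),
      el(0x0028, 0x1052, "DS", intercept),
      el(0x0028, 0x1053, "DS", 1),
      el(0x7FE0, 0x0010, "OW", pix)
    ))
    paths[k] <- file.path(out_dir, sprintf("slice-%03d.dcm", k))
    dcm_write(paths[k], sop_class, uids$sop[k], ds)
  }
  invisible(paths)
}

#' Write the phantom RT Structure Set
#'
#' Emits one ROIContour sequence per ROI in the spec; contour points are flat
#' `(x, y, z)` mm triplets lying on slice planes, and the referenced frame of
#' reference / series UIDs match the written series.
#'
#' @param spec a [phantom_spec()] whose series has been written (UIDs are
#'   derived deterministically from the spec, so the series must come from the
#'   same spec)
#' @param out_path file path for the RTSTRUCT
#' @return `out_path`, invisibly
#' @export
write_phantom_rtstruct <- function(spec, out_path) {
  stopifnot(inherits(spec, "phantom_spec"))
  uids <- phantom_uids(spec)
  sop_class_img <- SOP_CLASS[[spec$modality]]

  contour_image_item <- function(k) {
    list(el(0x0008, 0x1150, "UI", sop_class_img),
         el(0x0008, 0x1155, "UI", uids$sop[k + 1L]))
  }
  ssroi_items <- list(); contour_items <- list()
  for (i in seq_along(spec$rois)) {
    roi <- spec$rois[[i]]
    ssroi_items[[i]] <- list(
      el(0x3006, 0x0022, "IS", i),
      el(0x3006, 0x0024, "UI", uids$frame_of_reference),
      el(0x3006, 0x0026, "LO", roi$name),
      el(0x3006, 0x0036, "CS", "MANUAL"))
    polys <- roi_polygons(spec, roi)
    contour_seq <- list()
    for (j in seq_along(roi$slice_range)) {
      k <- roi$slice_range[j]
      for (pts in polys[[j]]) {
        contour_seq[[length(contour_seq) + 1L]] <- list(
          el(0x3006, 0x0016, "SQ", list(contour_image_item(k))),
          el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
          el(0x3006, 0x0046, "IS", nrow(pts)),
          el(0x3006, 0x0050, "DS", as.vector(t(pts))))
      }
    }
    contour_items[[i]] <- list(
      el(0x3006, 0x0040, "SQ", contour_seq),
      el(0x3006, 0x0084, "IS", i))
  }
  ref_for <- list(list(
    el(0x0020, 0x0052, "UI", uids$frame_of_reference),
    el(0x3006, 0x0012, "SQ", list(list(
      el(0x0008, 0x1150, "UI", "1.2.840.10008.3.1.2.3.1"),
      el(0x0008, 0x1155, "UI", uids$study),
      el(0x3006, 0x0014, "SQ", list(list(
        el(0x0020, 0x000E, "UI", uids$series)))))))))
  ds <- c(.common_elems(spec, uids, SOP_CLASS[["RTSTRUCT"]], uids$rtstruct), list(
    el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el(0x3006, 0x0002, "SH", "PhantomSS"),
    el(0x3006, 0x0010, "SQ", ref_for),
    el(0x3006, 0x0020, "SQ", ssroi_items),
    el(0x3006, 0x0039, "SQ", contour_items)
  ))
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  dcm_write(out_path, SOP_CLASS[["RTSTRUCT"]], uids$rtstruct, ds)
  invisible(out_path)
}

#' Generate a complete phantom case (series + RTSTRUCT)
#'
#' @inheritParams write_phantom_series
#' @return a list with `series_dir`, `rtstruct_path` and the `spec`
#' @export
make_case <- function(spec, out_dir) {
  series_dir <- file.path(out_dir, "series")
  write_phantom_series(spec, series_dir)
  rt <- file.path(out_dir, "rtstruct.dcm")
  write_phantom_rtstruct(spec, rt)
  list(series_dir = series_dir, rtstruct_path = rt, spec = spec)
}
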