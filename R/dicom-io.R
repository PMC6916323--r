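#' In-memory image volume
#'
#' A 3-D scalar grid with patient-space geometry. Voxel indices are 0-based
#' `(slice, row, col)`; a voxel center sits at
#' `origin + direction %*% (spacing * index)` with `direction` a 3x3 matrix of
#' unit column vectors for the slice, row and column axes (LPS).
#'
#' @param voxels 3-D numeric array `(slice, row, col)` in modality units
#' @param origin mm triplet, patient-space position of the first voxel center
#' @param spacing mm triplet `(between-slice, row, col)`, all > 0
#' @param direction 3x3 direction-cosine matrix (orthonormal columns)
#' @param modality,patient_id,series_uid,frame_of_reference_uid metadata
#' @return an object of class `image_volume`
#' @export
image_volume <- function(voxels, origin, spacing,
                         direction = cbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)),
                         modality = "CT", patient_id = "",
                         series_uid = "", frame_of_reference_uid = "") {
  stopifnot(length(dim(voxels)) == 3L, length(origin) == 3L,
            length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive on every axis")
  if (abs(abs(det(direction)) - 1) > 1e-6 ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction cosine matrix is not orthonormal")
  dimnames(direction) <- list(NULL, c("slice", "row", "col"))
  structure(list(voxels = voxels, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), direction = direction,
                 modality = modality, patient_id = patient_id,
                 series_uid = series_uid,
                 frame_of_reference_uid = frame_of_reference_uid),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s %s: %d x %d x %d voxels, spacing %.3g/%.3g/%.3g mm\n",
              x$modality, x$patient_id, dim(x$voxels)[1], dim(x$voxels)[2],
              dim(x$voxels)[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

.is_image_sop <- function(uid) uid %in% SOP_CLASS[c("CT", "PT", "MR")]

.decode_pixels <- function(ds, what) {
  rows <- dcm_require(ds, 0x0028, 0x0010, "Rows")
  cols <- dcm_require(ds, 0x0028, 0x0011, "Columns")
  signed <- dcm_get(ds, 0x0028, 0x0103, 0L) == 1L
  raw_pix <- dcm_require(ds, 0x7FE0, 0x0010, "PixelData")
  vals <- readBin(raw_pix, integer(), rows * cols, size = 2L,
                  signed = signed, endian = "little")
  slope <- dcm_get(ds, 0x0028, 0x1053, 1)
  intercept <- dcm_get(ds, 0x0028, 0x1052, 0)
  m <- matrix(vals * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)
  m
}

#' Read a DICOM image series into an [image_volume()]
#'
#' Slices are sorted by the projection of ImagePositionPatient onto the slice
#' normal (the cross product of the row and column direction cosines), so the
#' result is invariant to on-disk file order. Rescale slope/intercept are
#' applied. The series must be geometrically consistent: a single
#' SeriesInstanceUID, uniform in-plane geometry, and uniform slice gaps.
#'
#' @param dir directory containing the `.dcm` files of exactly one series
#' @param gap_tol tolerance (mm) for slice-gap uniformity
#' @return an [image_volume()]
#' @export
read_series <- function(dir, gap_tol = 1e-3) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) stop("no DICOM files found in ", dir)
  parsed <- lapply(files, function(f) dcm_read(f)$data)
  is_img <- vapply(parsed, function(ds)
    .is_image_sop(dcm_get(ds, 0x0008, 0x0016, "")), logical(1))
  parsed <- parsed[is_img]; files <- files[is_img]
  if (length(parsed) == 0L) stop("no image-storage DICOM files in ", dir)

  series_uids <- vapply(parsed, function(ds)
    dcm_require(ds, 0x0020, 0x000E, "SeriesInstanceUID"), character(1))
  if (length(unique(series_uids)) > 1L)
    stop("directory mixes multiple series: ",
         paste(unique(series_uids), collapse = ", "))

  iop <- dcm_require(parsed[[1]], 0x0020, 0x0037, "ImageOrientationPatient")
  d_col <- iop[1:3]; d_row <- iop[4:6]
  normal <- c(d_col[2] * d_row[3] - d_col[3] * d_row[2],
              d_col[3] * d_row[1] - d_col[1] * d_row[3],
              d_col[1] * d_row[2] - d_col[2] * d_row[1])
  ipp <- t(vapply(parsed, function(ds)
    dcm_require(ds, 0x0020, 0x0032, "ImagePositionPatient"), numeric(3)))
  pos <- as.vector(ipp %*% normal)
  ord <- order(pos)
  parsed <- parsed[ord]; ipp <- ipp[ord, , drop = FALSE]; pos <- pos[ord]

  if (length(pos) > 1L) {
    gaps <- diff(pos)
    if (any(gaps <= 0)) stop("slice positions are not strictly monotone ",
                             "along the slice normal")
    if (max(gaps) - min(gaps) > gap_tol)
      stop("non-uniform slice gaps beyond tolerance: ",
           paste(sprintf("%.4f", gaps), collapse = ", "), " mm")
    slice_spacing <- mean(gaps)
  } else {
    slice_spacing <- dcm_get(parsed[[1]], 0x0018, 0x0050, 1)
  }
  ps <- dcm_require(parsed[[1]], 0x0028, 0x0030, "PixelSpacing")
  slices <- lapply(parsed, .decode_pixels)
  rows <- nrow(slices[[1]]); cols <- ncol(slices[[1]])
  vox <- array(0, dim = c(length(slices), rows, cols))
  for (k in seq_along(slices)) vox[k, , ] <- slices[[k]]

  image_volume(
    voxels = vox, origin = ipp[1, ],
    spacing = c(slice_spacing, ps[1], ps[2]),
    direction = cbind(normal, d_row, d_col),
    modality = dcm_get(parsed[[1]], 0x0008, 0x0060, ""),
    patient_id = dcm_get(parsed[[1]], 0x0010, 0x0020, ""),
    series_uid = series_uids[1],
    frame_of_reference_uid = dcm_get(parsed[[1]], 0x0020, 0x0052, ""))
}

.normalize_roi_name <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Read an RT Structure Set
#'
#' Every ContourSequence is converted to planar contours of `(x, y, z)` mm
#' triplets; ROI names are whitespace-normalized. Contours with fewer than 3
#' points are dropped with a warning rather than failing the whole file.
#'
#' @param path path to the RTSTRUCT DICOM file
#' @return a list of class `structure_set` with `rois` (each with `name`,
#'   `roi_number`, `contours`), `referenced_series_uid`,
#'   `referenced_frame_of_reference_uid`, `source_file`
#' @export
read_structset <- function(path) {
  ds <- dcm_read(path)$data
  if (!identical(dcm_get(ds, 0x0008, 0x0016, ""), SOP_CLASS[["RTSTRUCT"]]))
    stop("not an RT Structure Set storage file: ", path)

  ref_for_uid <- ""; ref_series_uid <- ""
  for (it in dcm_get(ds, 0x3006, 0x0010, list())) {
    ref_for_uid <- dcm_get(it, 0x0020, 0x0052, ref_for_uid)
    for (st in dcm_get(it, 0x3006, 0x0012, list()))
      for (se in dcm_get(st, 0x3006, 0x0014, list()))
        ref_series_uid <- dcm_get(se, 0x0020, 0x000E, ref_series_uid)
  }

  meta <- list()
  for (it in dcm_get(ds, 0x3006, 0x0020, list())) {
    num <- dcm_get(it, 0x3006, 0x0022, NA)
    meta[[as.character(num)]] <- .normalize_roi_name(
      dcm_get(it, 0x3006, 0x0026, paste0("ROI-", num)))
  }

  rois <- list()
  for (it in dcm_get(ds, 0x3006, 0x0039, list())) {
    num <- dcm_get(it, 0x3006, 0x0084, NA)
    name <- meta[[as.character(num)]] %||% paste0("ROI-", num)
    contours <- list()
    for (cs in dcm_get(it, 0x3006, 0x0040, list())) {
      pts <- dcm_get(cs, 0x3006, 0x0050, numeric(0))
      if (length(pts) < 9L) {
        rs_log("warning", "dropping degenerate contour (<3 points) in ROI ", name)
        next
      }
      contours[[length(contours) + 1L]] <- matrix(pts, ncol = 3L, byrow = TRUE)
    }
    rois[[length(rois) + 1L]] <- list(name = name, roi_number = num,
                                      contours = contours)
  }
  names(rois) <- vapply(rois, `[[`, character(1), "name")
  structure(list(rois = rois, referenced_series_uid = ref_series_uid,
                 referenced_frame_of_reference_uid = ref_for_uid,
                 source_file = path),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROI(s): %s\n", length(x$rois),
              paste(names(x$rois), collapse = ", ")))
  invisible(x)
}

#' Pair image series with their RTSTRUCT files under a directory tree
#'
#' Pairing precedence: shared FrameOfReferenceUID, then referenced
#' SeriesInstanceUID, then co-location in the same case directory. Unmatched
#' items are logged, not fatal; if two RTSTRUCTs claim the same series both
#' pairings are emitted with a warning.
#'
#' @param root directory scanned recursively
#' @return list of pairings, each with `series_dir`, `rtstruct_path`,
#'   `matched_by`
#' @export
match_cases <- function(root) {
  files <- list.files(root, pattern = "\\.dcm$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  info <- lapply(files, function(f) {
    ds <- tryCatch(dcm_read(f)$data, error = function(e) NULL)
    if (is.null(ds)) return(NULL)
    sop <- dcm_get(ds, 0x0008, 0x0016, "")
    if (identical(sop, SOP_CLASS[["RTSTRUCT"]])) {
      ref_for <- ""; ref_series <- ""
      for (it in dcm_get(ds, 0x3006, 0x0010, list())) {
        ref_for <- dcm_get(it, 0x0020, 0x0052, ref_for)
        for (st in dcm_get(it, 0x3006, 0x0012, list()))
          for (se in dcm_get(st, 0x3006, 0x0014, list()))
            ref_series <- dcm_get(se, 0x0020, 0x000E, ref_series)
      }
      list(kind = "rtstruct", path = f, ref_for = ref_for,
           ref_series = ref_series)
    } else if (.is_image_sop(sop)) {
      list(kind = "image", path = f,
           series = dcm_get(ds, 0x0020, 0x000E, ""),
           frame_of_reference = dcm_get(ds, 0x0020, 0x0052, ""))
    } else NULL
  })
  info <- Filter(Negate(is.null), info)
  imgs <- Filter(function(x) x$kind == "image", info)
  rts <- Filter(function(x) x$kind == "rtstruct", info)
  if (length(imgs) == 0L || length(rts) == 0L)
    stop("need at least one image series and one RTSTRUCT under ", root)

  series <- unique(data.frame(
    dir = dirname(vapply(imgs, `[[`, character(1), "path")),
    uid = vapply(imgs, `[[`, character(1), "series"),
    for_uid = vapply(imgs, `[[`, character(1), "frame_of_reference"),
    stringsAsFactors = FALSE))

  pairings <- list()
  for (rt in rts) {
    hit <- which(series$for_uid != "" & series$for_uid == rt$ref_for)
    matched_by <- "frame_of_reference"
    if (length(hit) == 0L) {
      hit <- which(series$uid != "" & series$uid == rt$ref_series)
      matched_by <- "series_uid"
    }
    if (length(hit) == 0L) {
      case_dir <- dirname(rt$path)
      hit <- which(startsWith(series$dir, case_dir))
      matched_by <- "directory_fallback"
      if (length(hit) > 0L)
        rs_log("warning", "RTSTRUCT ", basename(rt$path),
               " matched by directory co-location only")
    }
    if (length(hit) == 0L) {
      rs_log("warning", "unmatched RTSTRUCT: ", rt$path)
      next
    }
    for (h in hit)
      pairings[[length(pairings) + 1L]] <- list(
        series_dir = series$dir[h], rtstruct_path = rt$path,
        matched_by = matched_by)
  }
  claimed <- vapply(pairings, `[[`, character(1), "series_dir")
  for (d in unique(claimed[duplicated(claimed)]))
    rs_log("warning", "series ", d, " is claimed by multiple RTSTRUCTs; ",
           "emitting all pairings")
  pairings
}

#' Filter ROIs of a structure set by glob patterns
#'
#' Matching is case-insensitive; `exclude` wins over `include`; an empty
#' `include` keeps everything.
#'
#' @param ss a [read_structset()] result
#' @param include,exclude character vectors of glob patterns
#' @return the filtered `structure_set`
#' @export
select_rois <- function(ss, include = character(0), exclude = character(0)) {
  nm <- names(ss$rois)
  match_any <- function(patterns, x) {
    if (length(patterns) == 0L) return(rep(FALSE, length(x)))
    Reduce(`|`, lapply(patterns, function(p)
      grepl(utils::glob2rx(p), x, ignore.case = TRUE)))
  }
  keep <- if (length(include) == 0L) rep(TRUE, length(nm))
          else match_any(include, nm)
  keep <- keep & !match_any(exclude, nm)
  ss$rois <- ss$rois[keep]
  ss
}
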