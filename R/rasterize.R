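#' Binary mask on an image grid
#'
#' @param bits 3-D logical array congruent with the volume grid
#' @param roi_name name of the ROI the mask represents
#' @param origin,spacing,direction grid geometry copied from the volume
#' @return an object of class `binary_mask`
#' @export
binary_mask <- function(bits, roi_name, origin, spacing, direction) {
  stopifnot(is.logical(bits), length(dim(bits)) == 3L)
  structure(list(bits = bits, roi_name = roi_name, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), direction = direction),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> '%s': %d / %d voxels set\n", x$roi_name,
              sum(x$bits), length(x$bits)))
  invisible(x)
}

mask_from_volume <- function(bits, roi_name, vol) {
  binary_mask(bits, roi_name, vol$origin, vol$spacing, vol$direction)
}

.grids_congruent <- function(a, b) {
  identical(dim(a$bits %||% a$voxels), dim(b$bits %||% b$voxels)) &&
    max(abs(a$origin - b$origin)) < 1e-6 &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$direction - b$direction)) < 1e-9
}

# contour points (patient mm, N x 3) -> continuous 0-based index coords
.points_to_index <- function(pts, vol) {
  rel <- sweep(pts, 2, vol$origin, "-") %*% vol$direction
  sweep(rel, 2, vol$spacing, "/")
}

#' Rasterize a planar-contour ROI onto an image grid
#'
#' A voxel is set iff its center is inside the even-odd (parity) fill of the
#' union of the polygons assigned to its slice, evaluated in the slice plane.
#' Multiple polygons on one slice combine by the even-odd rule, so inner
#' contours cut holes. Slices with no contour stay empty. Centers exactly on a
#' polygon edge are resolved by a consistent half-open rule (left/top edges
#' count as inside), the usual scan-line convention.
#'
#' @param roi one element of a [read_structset()]'s `rois` list
#' @param vol the [image_volume()] defining the grid
#' @param slice_tol contour-to-slice assignment tolerance as a fraction of the
#'   slice spacing (default half a spacing)
#' @return a [binary_mask()]
#' @export
rasterize <- function(roi, vol, slice_tol = 0.5) {
  dims <- dim(vol$voxels)
  bits <- array(FALSE, dim = dims)
  polys_by_slice <- vector("list", dims[1])
  for (ci in seq_along(roi$contours)) {
    idx <- .points_to_index(roi$contours[[ci]], vol)
    k_mean <- mean(idx[, 1])
    k <- round(k_mean)
    if (k < 0 || k >= dims[1] || abs(k_mean - k) > slice_tol + 1e-9)
      stop(sprintf("contour %d of ROI '%s' lies %.3f slice-spacings from the nearest image slice",
                   ci, roi$name, abs(k_mean - round(k_mean))))
    if (max(abs(idx[, 1] - k_mean)) > 1e-6)
      rs_log("warning", "tilted contour in ROI '", roi$name,
             "' projected onto slice ", k)
    polys_by_slice[[k + 1L]] <- c(polys_by_slice[[k + 1L]],
                                  list(idx[, c(2, 3), drop = FALSE]))
  }
  if (length(roi$contours) == 0L)
    rs_log("warning", "ROI '", roi$name, "' has no contours; mask is empty")
  for (k in seq_len(dims[1])) {
    polys <- polys_by_slice[[k]]
    if (is.null(polys)) next
    bits[k, , ] <- .fill_slice(polys, dims[2], dims[3])
  }
  mask_from_volume(bits, roi$name, vol)
}

# even-odd scan-line fill of polygons given in continuous (row, col) index
# coordinates; voxel centers are at integer (r, c), 0-based
.fill_slice <- function(polys, nr, nc) {
  edges <- do.call(rbind, lapply(polys, function(p) {
    q <- rbind(p, p[1, , drop = FALSE])
    n <- nrow(p)
    cbind(r1 = q[1:n, 1], c1 = q[1:n, 2], r2 = q[2:(n + 1), 1],
          c2 = q[2:(n + 1), 2])
  }))
  out <- matrix(FALSE, nr, nc)
  keep <- edges[, "r1"] != edges[, "r2"]
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) return(out)
  rmin <- max(0L, ceiling(min(edges[, c("r1", "r2")])))
  rmax <- min(nr - 1L, floor(max(edges[, c("r1", "r2")])))
  if (rmin > rmax) return(out)
  cols <- 0:(nc - 1L)
  for (r in rmin:rmax) {
    # half-open row rule: edge spans r iff r1 <= r < r2 or r2 <= r < r1
    act <- (edges[, "r1"] <= r & r < edges[, "r2"]) |
           (edges[, "r2"] <= r & r < edges[, "r1"])
    if (!any(act)) next
    e <- edges[act, , drop = FALSE]
    cross <- e[, "c1"] + (r - e[, "r1"]) * (e[, "c2"] - e[, "c1"]) /
      (e[, "r2"] - e[, "r1"])
    cross <- sort(cross)
    # inside iff an odd number of crossings lie strictly right of the center
    n_le <- findInterval(cols, cross)
    out[r + 1L, ] <- ((length(cross) - n_le) %% 2L) == 1L
  }
  out
}

#' Independent ray-casting rasterization oracle
#'
#' Same contract as [rasterize()] but implemented by casting a ray from every
#' voxel center and counting polygon-edge crossings one voxel at a time, with
#' no code shared with the scan-line path. Used to validate mask conversion
#' (the in-repo analogue of cross-software mask comparisons).
#'
#' @inheritParams rasterize
#' @return a [binary_mask()]
#' @export
oracle_rasterize <- function(roi, vol, slice_tol = 0.5) {
  dims <- dim(vol$voxels)
  bits <- array(FALSE, dim = dims)
  # independent geometry mapping: solve origin + D (s*i) = x per point
  Dinv <- solve(vol$direction)
  for (contour in roi$contours) {
    ctr_idx <- t(apply(contour, 1L, function(x)
      (Dinv %*% (x - vol$origin)) / vol$spacing))
    k <- as.integer(round(mean(ctr_idx[, 1])))
    if (k < 0L || k >= dims[1] ||
        abs(mean(ctr_idx[, 1]) - k) > slice_tol + 1e-9)
      stop("oracle: contour off-grid for ROI '", roi$name, "'")
    pr <- ctr_idx[, 2]; pc <- ctr_idx[, 3]
    n <- length(pr)
    for (r in 0:(dims[2] - 1L)) {
      for (cc in 0:(dims[3] - 1L)) {
        crossings <- 0L
        for (i in seq_len(n)) {
          j <- if (i == n) 1L else i + 1L
          straddles <- (pr[i] <= r && r < pr[j]) || (pr[j] <= r && r < pr[i])
          if (straddles) {
            cint <- pc[i] + (r - pr[i]) * (pc[j] - pc[i]) / (pr[j] - pr[i])
            if (cint > cc) crossings <- crossings + 1L
          }
        }
        if (crossings %% 2L == 1L)
          bits[k + 1L, r + 1L, cc + 1L] <- !bits[k + 1L, r + 1L, cc + 1L]
      }
    }
  }
  mask_from_volume(bits, roi$name, vol)
}

#' Dice similarity coefficient between two binary masks
#'
#' `D = 2|A intersect B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param a,b [binary_mask()] objects on congruent grids
#' @return proportion in `[0, 1]`
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!.grids_congruent(a, b)) stop("dice: masks live on different grids")
  na <- sum(a$bits); nb <- sum(b$bits)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$bits & b$bits) / (na + nb)
}
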