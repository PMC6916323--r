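#' Gray-level co-occurrence matrix features (22)
#'
#' 3-D co-occurrence at distance 1 over the 13 unique direction vectors.
#' Each direction's matrix is accumulated symmetrically (both voxel orders),
#' normalized to probabilities, features are computed per direction and then
#' averaged with equal weights. Directions contributing no valid voxel pair
#' are dropped from the average.
#'
#' @param d a `discretized_region`
#' @return data.frame with columns `family`, `name`, `value` (22 rows)
#' @export
glcm_features <- function(d) {
  ng <- d$ng
  per_dir <- apply(DIRECTIONS_13, 1L, function(off) {
    P <- glcm_matrix(d$grid, ng, off)
    if (sum(P) == 0) return(NULL)
    .glcm_stats(P / sum(P))
  }, simplify = FALSE)
  vals <- .average_directions(per_dir)
  if (is.null(vals)) {
    rs_log("warning", "no co-occurring voxel pairs; GLCM features are NaN")
    vals <- stats::setNames(rep(NaN, length(.glcm_names)), .glcm_names)
  }
  feature_rows("glcm", vals)
}

#' Co-occurrence count matrix for one direction
#'
#' @param grid integer level array with `NA` outside the region
#' @param ng number of gray levels
#' @param off length-3 integer offset `(slice, row, col)`
#' @return `ng` x `ng` symmetric count matrix
#' @export
glcm_matrix <- function(grid, ng, off) {
  nb <- shift_grid(grid, off)
  ok <- !is.na(grid) & !is.na(nb)
  i <- grid[ok]; j <- nb[ok]
  cnt <- tabulate((j - 1L) * ng + i, ng * ng)
  P <- matrix(cnt, ng, ng)
  P + t(P)
}

.glcm_names <- c(
  "Autocorrelation", "Joint Average", "Cluster Prominence", "Cluster Shade",
  "Cluster Tendency", "Contrast", "Correlation", "Difference Average",
  "Difference Entropy", "Difference Variance", "Joint Energy", "Joint Entropy",
  "Informational Measure of Correlation 1",
  "Informational Measure of Correlation 2",
  "Inverse Difference Moment", "Inverse Difference Moment Normalized",
  "Inverse Difference", "Inverse Difference Normalized", "Inverse Variance",
  "Maximum Probability", "Sum Entropy", "Sum of Squares")

.glcm_stats <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  # diagonal-band marginals
  diffk <- 0:(ng - 1)
  pxmy <- vapply(diffk, function(k) sum(p[abs(i - j) == k]), numeric(1))
  sumk <- 2:(2 * ng)
  pxpy <- vapply(sumk, function(k) sum(p[(i + j) == k]), numeric(1))

  hx <- .entropy2(px); hy <- .entropy2(py)
  hxy <- .entropy2(p)
  pp <- px[i] * py[j]
  nz <- p > 0 & pp > 0
  hxy1 <- -sum(p[nz] * log2(pp[nz]))
  nz2 <- pp > 0
  hxy2 <- -sum(pp[nz2] * log2(pp[nz2]))

  da <- sum(diffk * pxmy)
  corr <- if (sigx * sigy == 0) 1 else (sum(i * j * p) - mux * muy) / (sigx * sigy)
  imc1 <- if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  imc2 <- if (hxy2 < hxy) 0 else sqrt(1 - exp(-2 * (hxy2 - hxy)))

  off_diag <- abs(i - j) > 0
  stats::setNames(c(
    sum(i * j * p),
    mux,
    sum((i + j - mux - muy)^4 * p),
    sum((i + j - mux - muy)^3 * p),
    sum((i + j - mux - muy)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    .entropy2(pxmy),
    sum((diffk - da)^2 * pxmy),
    sum(p^2),
    hxy,
    imc1,
    imc2,
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + ((i - j)^2 / ng^2))),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + abs(i - j) / ng)),
    sum(p[off_diag] / (i[off_diag] - j[off_diag])^2),
    max(p),
    .entropy2(pxpy),
    sum((i - mux)^2 * p)),
    .glcm_names)
}
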