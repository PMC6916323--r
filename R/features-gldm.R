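#' Gray-level dependence matrix features (14)
#'
#' The dependence of a voxel is the number of its 26-neighbors inside the
#' region whose gray level differs by at most `alpha` (default 0). The
#' dependence matrix counts voxels by (level, dependence); column `j`
#' corresponds to dependence `j - 1`.
#'
#' @param d a `discretized_region`
#' @param alpha gray-level difference tolerance for dependence
#' @return data.frame with columns `family`, `name`, `value` (14 rows)
#' @export
gldm_features <- function(d, alpha = 0L) {
  P <- gldm_matrix(d$grid, d$ng, alpha)
  ng <- nrow(P); nd <- ncol(P)
  nz <- sum(P)
  p <- P / nz
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  ri <- rowSums(P); rj <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  feature_rows("gldm", stats::setNames(c(
    sum(P / j^2) / nz,
    sum(P * j^2) / nz,
    sum(ri^2) / nz,
    sum(rj^2) / nz,
    sum(rj^2) / nz^2,
    sum(p * (i - mu_i)^2),
    sum(p * (j - mu_j)^2),
    .entropy2(as.vector(p)),
    sum(P / i^2) / nz,
    sum(P * i^2) / nz,
    sum(P / (i^2 * j^2)) / nz,
    sum(P * i^2 / j^2) / nz,
    sum(P * j^2 / i^2) / nz,
    sum(P * i^2 * j^2) / nz),
    .gldm_names))
}

.gldm_names <- c(
  "Small Dependence Emphasis", "Large Dependence Emphasis",
  "Gray Level Non-Uniformity", "Dependence Non-Uniformity",
  "Dependence Non-Uniformity Normalized", "Gray Level Variance",
  "Dependence Variance", "Dependence Entropy", "Low Gray Level Emphasis",
  "High Gray Level Emphasis", "Small Dependence Low Gray Level Emphasis",
  "Small Dependence High Gray Level Emphasis",
  "Large Dependence Low Gray Level Emphasis",
  "Large Dependence High Gray Level Emphasis")

#' Dependence count matrix
#'
#' @inheritParams glcm_matrix
#' @param alpha gray-level difference tolerance
#' @return `ng` x `max_dependence + 1` count matrix; column `j` holds voxels
#'   with dependence `j - 1`
#' @export
gldm_matrix <- function(grid, ng, alpha = 0L) {
  dims <- dim(grid)
  dep <- array(0L, dims)
  offsets <- rbind(DIRECTIONS_13, -DIRECTIONS_13)
  for (di in seq_len(nrow(offsets))) {
    nb <- shift_grid(grid, offsets[di, ])
    ok <- !is.na(grid) & !is.na(nb) & abs(grid - nb) <= alpha
    dep[ok] <- dep[ok] + 1L
  }
  lvl <- grid[!is.na(grid)]
  dp <- dep[!is.na(grid)]
  nd <- max(dp) + 1L
  matrix(tabulate(dp * ng + lvl, ng * nd), ng, nd)
}
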