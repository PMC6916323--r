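#' Gray-level run-length matrix features (16)
#'
#' Runs are maximal collinear segments of equal gray level along each of the
#' 13 unique 3-D directions; a run is broken by voxels outside the region.
#' Features are computed per direction and averaged with equal weights.
#'
#' @param d a `discretized_region`
#' @return data.frame with columns `family`, `name`, `value` (16 rows)
#' @export
glrlm_features <- function(d) {
  np <- length(d$levels)
  per_dir <- apply(DIRECTIONS_13, 1L, function(off) {
    P <- glrlm_matrix(d$grid, d$ng, off)
    if (sum(P) == 0) return(NULL)
    .rl_stats(P, np, .glrlm_names)
  }, simplify = FALSE)
  vals <- .average_directions(per_dir)
  feature_rows("glrlm", vals)
}

#' Run-length count matrix for one direction
#'
#' @inheritParams glcm_matrix
#' @return `ng` x `max_run_length` count matrix
#' @export
glrlm_matrix <- function(grid, ng, off) {
  dims <- dim(grid)
  k <- as.vector(slice.index(grid, 1)); r <- as.vector(slice.index(grid, 2))
  cc <- as.vector(slice.index(grid, 3))
  steps_back <- function(coord, n, dd) {
    if (dd == 1L) coord - 1L
    else if (dd == -1L) n - coord
    else rep(.Machine$integer.max, length(coord))
  }
  t_back <- pmin(steps_back(k, dims[1], off[1]),
                 steps_back(r, dims[2], off[2]),
                 steps_back(cc, dims[3], off[3]))
  line_id <- (k - t_back * off[1]) +
    (r - t_back * off[2] - 1L) * dims[1] +
    (cc - t_back * off[3] - 1L) * dims[1] * dims[2]
  ord <- order(line_id, t_back)
  v <- as.vector(grid)[ord]
  lid <- line_id[ord]
  n <- length(v)
  same <- c(FALSE, lid[-1] == lid[-n] & !is.na(v[-1]) & !is.na(v[-n]) &
              v[-1] == v[-n])
  run_id <- cumsum(!same)
  starts <- which(!same)
  run_level <- v[starts]
  run_len <- tabulate(run_id)
  keep <- !is.na(run_level)
  run_level <- run_level[keep]; run_len <- run_len[keep]
  nl <- max(run_len)
  matrix(tabulate((run_len - 1L) * ng + run_level, ng * nl), ng, nl)
}

.glrlm_names <- c(
  "Short Run Emphasis", "Long Run Emphasis", "Gray Level Non-Uniformity",
  "Gray Level Non-Uniformity Normalized", "Run Length Non-Uniformity",
  "Run Length Non-Uniformity Normalized", "Run Percentage",
  "Gray Level Variance", "Run Variance", "Run Entropy",
  "Low Gray Level Run Emphasis", "High Gray Level Run Emphasis",
  "Short Run Low Gray Level Emphasis", "Short Run High Gray Level Emphasis",
  "Long Run Low Gray Level Emphasis", "Long Run High Gray Level Emphasis")

.glszm_names <- c(
  "Small Area Emphasis", "Large Area Emphasis", "Gray Level Non-Uniformity",
  "Gray Level Non-Uniformity Normalized", "Size Zone Non-Uniformity",
  "Size Zone Non-Uniformity Normalized", "Zone Percentage",
  "Gray Level Variance", "Zone Variance", "Zone Entropy",
  "Low Gray Level Zone Emphasis", "High Gray Level Zone Emphasis",
  "Small Area Low Gray Level Emphasis", "Small Area High Gray Level Emphasis",
  "Large Area Low Gray Level Emphasis", "Large Area High Gray Level Emphasis")

# shared statistics for run-length and size-zone matrices: rows are gray
# levels i, columns are run lengths / zone sizes j
.rl_stats <- function(P, np, names) {
  ng <- nrow(P); nl <- ncol(P)
  nr <- sum(P)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- P / nr
  ri <- rowSums(P); rj <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  stats::setNames(c(
    sum(P / j^2) / nr,
    sum(P * j^2) / nr,
    sum(ri^2) / nr,
    sum(ri^2) / nr^2,
    sum(rj^2) / nr,
    sum(rj^2) / nr^2,
    nr / np,
    sum(p * (i - mu_i)^2),
    sum(p * (j - mu_j)^2),
    .entropy2(as.vector(p)),
    sum(P / i^2) / nr,
    sum(P * i^2) / nr,
    sum(P / (i^2 * j^2)) / nr,
    sum(P * i^2 / j^2) / nr,
    sum(P * j^2 / i^2) / nr,
    sum(P * i^2 * j^2) / nr),
    names)
}
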