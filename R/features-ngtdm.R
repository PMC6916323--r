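#' Neighborhood gray-tone difference matrix features (5)
#'
#' For each gray level `i`, `s_i` sums `|i - mean of 26-neighborhood|` over
#' region voxels of level `i`; voxels with no in-region neighbor are excluded
#' from the tally. Degenerate cases follow fixed conventions: a single
#' occupied level yields Contrast and Busyness 0, and a vanishing `sum(p*s)`
#' caps Coarseness at 1e6 (the 1/epsilon guard with epsilon = 1e-6).
#'
#' @param d a `discretized_region`
#' @return data.frame with columns `family`, `name`, `value` (5 rows)
#' @export
ngtdm_features <- function(d) {
  tb <- ngtdm_table(d$grid, d$ng)
  n_i <- tb$n_i; s_i <- tb$s_i
  nv <- sum(n_i)
  if (nv == 0L) {
    rs_log("warning", "no voxel has an in-region neighbor; NGTDM features NaN")
    return(feature_rows("ngtdm", stats::setNames(rep(NaN, 5), .ngtdm_names)))
  }
  p_i <- n_i / nv
  act <- which(p_i > 0)
  ngp <- length(act)
  i <- act
  ps <- sum(p_i * s_i)

  coarseness <- if (ps == 0) 1e6 else 1 / ps
  if (ngp > 1) {
    pij <- outer(p_i[act], p_i[act])
    d2 <- outer(i, i, `-`)^2
    contrast <- sum(pij * d2) / (ngp * (ngp - 1)) * sum(s_i) / nv
    ipi <- i * p_i[act]
    busyness <- ps / sum(abs(outer(ipi, ipi, `-`)))
    num <- outer(p_i[act] * s_i[act], p_i[act] * s_i[act], `+`)
    den <- outer(p_i[act], p_i[act], `+`)
    complexity <- sum(abs(outer(i, i, `-`)) * num / den) / nv
    strength <- if (sum(s_i) == 0) 0 else sum(den * d2) / sum(s_i)
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  feature_rows("ngtdm", stats::setNames(
    c(coarseness, contrast, busyness, complexity, strength), .ngtdm_names))
}

.ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                  "Strength")

#' NGTDM tally table
#'
#' @inheritParams glcm_matrix
#' @return list with `n_i` (voxel counts per level, neighbor-bearing voxels
#'   only) and `s_i` (summed absolute differences from the neighborhood mean)
#' @export
ngtdm_table <- function(grid, ng) {
  dims <- dim(grid)
  nbsum <- array(0, dims)
  nbcnt <- array(0L, dims)
  offsets <- rbind(DIRECTIONS_13, -DIRECTIONS_13)
  for (di in seq_len(nrow(offsets))) {
    nb <- shift_grid(grid, offsets[di, ])
    has <- !is.na(nb)
    nbsum[has] <- nbsum[has] + nb[has]
    nbcnt <- nbcnt + has
  }
  ok <- !is.na(grid) & nbcnt > 0L
  lvl <- grid[ok]
  abar <- nbsum[ok] / nbcnt[ok]
  n_i <- tabulate(lvl, ng)
  s_i <- vapply(seq_len(ng), function(l) sum(abs(l - abar)[lvl == l]),
                numeric(1))
  list(n_i = n_i, s_i = s_i)
}
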