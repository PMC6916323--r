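# Brute-force enumeration oracles for the texture matrices. Deliberately
# naive (triple loops, queue flood fill), sharing no code with the package
# implementations.

.nb26 <- as.matrix(expand.grid(dk = -1:1, dr = -1:1, dc = -1:1))
.nb26 <- .nb26[rowSums(abs(.nb26)) > 0, ]

oracle_glcm_matrix <- function(grid, ng, off) {
  dims <- dim(grid)
  P <- matrix(0, ng, ng)
  for (k in seq_len(dims[1])) for (r in seq_len(dims[2]))
    for (cc in seq_len(dims[3])) {
      v <- grid[k, r, cc]
      if (is.na(v)) next
      for (sgn in c(1, -1)) {
        k2 <- k + sgn * off[1]; r2 <- r + sgn * off[2]; c2 <- cc + sgn * off[3]
        if (k2 < 1 || k2 > dims[1] || r2 < 1 || r2 > dims[2] ||
            c2 < 1 || c2 > dims[3]) next
        w <- grid[k2, r2, c2]
        if (!is.na(w)) P[v, w] <- P[v, w] + 1
      }
    }
  P
}

oracle_joint_entropy <- function(P) {
  p <- P / sum(P)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) tot <- tot - p[i, j] * log2(p[i, j])
  tot
}

oracle_glrlm_matrix <- function(grid, ng, off) {
  dims <- dim(grid)
  runs_level <- integer(0); runs_len <- integer(0)
  inb <- function(k, r, cc)
    k >= 1 && k <= dims[1] && r >= 1 && r <= dims[2] && cc >= 1 && cc <= dims[3]
  for (k in seq_len(dims[1])) for (r in seq_len(dims[2]))
    for (cc in seq_len(dims[3])) {
      v <- grid[k, r, cc]
      if (is.na(v)) next
      # run starts here iff the predecessor along off is not the same level
      pk <- k - off[1]; pr <- r - off[2]; pc <- cc - off[3]
      if (inb(pk, pr, pc) && !is.na(grid[pk, pr, pc]) &&
          grid[pk, pr, pc] == v) next
      len <- 1L
      nk <- k + off[1]; nr2 <- r + off[2]; nc2 <- cc + off[3]
      while (inb(nk, nr2, nc2) && !is.na(grid[nk, nr2, nc2]) &&
             grid[nk, nr2, nc2] == v) {
        len <- len + 1L
        nk <- nk + off[1]; nr2 <- nr2 + off[2]; nc2 <- nc2 + off[3]
      }
      runs_level <- c(runs_level, v); runs_len <- c(runs_len, len)
    }
  P <- matrix(0, ng, max(runs_len))
  for (i in seq_along(runs_level))
    P[runs_level[i], runs_len[i]] <- P[runs_level[i], runs_len[i]] + 1
  P
}

oracle_zones <- function(grid) {
  dims <- dim(grid)
  seen <- array(FALSE, dims)
  zones <- list()
  for (k in seq_len(dims[1])) for (r in seq_len(dims[2]))
    for (cc in seq_len(dims[3])) {
      if (is.na(grid[k, r, cc]) || seen[k, r, cc]) next
      lvl <- grid[k, r, cc]
      queue <- list(c(k, r, cc)); seen[k, r, cc] <- TRUE; size <- 0L
      while (length(queue) > 0L) {
        cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
        for (ni in seq_len(nrow(.nb26))) {
          p <- cur + .nb26[ni, ]
          if (any(p < 1) || any(p > dims)) next
          if (seen[p[1], p[2], p[3]]) next
          w <- grid[p[1], p[2], p[3]]
          if (!is.na(w) && w == lvl) {
            seen[p[1], p[2], p[3]] <- TRUE
            queue[[length(queue) + 1L]] <- p
          }
        }
      }
      zones[[length(zones) + 1L]] <- c(level = lvl, size = size)
    }
  zones
}

oracle_glszm_matrix <- function(grid, ng) {
  zones <- oracle_zones(grid)
  sizes <- vapply(zones, `[[`, numeric(1), "size")
  P <- matrix(0, ng, max(sizes))
  for (z in zones) P[z["level"], z["size"]] <- P[z["level"], z["size"]] + 1
  P
}

oracle_gldm_matrix <- function(grid, ng, alpha = 0) {
  dims <- dim(grid)
  lv <- integer(0); dp <- integer(0)
  for (k in seq_len(dims[1])) for (r in seq_len(dims[2]))
    for (cc in seq_len(dims[3])) {
      v <- grid[k, r, cc]
      if (is.na(v)) next
      dep <- 0L
      for (ni in seq_len(nrow(.nb26))) {
        p <- c(k, r, cc) + .nb26[ni, ]
        if (any(p < 1) || any(p > dims)) next
        w <- grid[p[1], p[2], p[3]]
        if (!is.na(w) && abs(w - v) <= alpha) dep <- dep + 1L
      }
      lv <- c(lv, v); dp <- c(dp, dep)
    }
  P <- matrix(0, ng, max(dp) + 1L)
  for (i in seq_along(lv)) P[lv[i], dp[i] + 1L] <- P[lv[i], dp[i] + 1L] + 1
  P
}

oracle_ngtdm_table <- function(grid, ng) {
  dims <- dim(grid)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (k in seq_len(dims[1])) for (r in seq_len(dims[2]))
    for (cc in seq_len(dims[3])) {
      v <- grid[k, r, cc]
      if (is.na(v)) next
      vals <- numeric(0)
      for (ni in seq_len(nrow(.nb26))) {
        p <- c(k, r, cc) + .nb26[ni, ]
        if (any(p < 1) || any(p > dims)) next
        w <- grid[p[1], p[2], p[3]]
        if (!is.na(w)) vals <- c(vals, w)
      }
      if (length(vals) == 0L) next
      n_i[v] <- n_i[v] + 1
      s_i[v] <- s_i[v] + abs(v - mean(vals))
    }
  list(n_i = n_i, s_i = s_i)
}

# random level grid with NA holes, dims <= 5^3
random_level_grid <- function(max_dim = 5L, ng = 4L, p_na = 0.2) {
  dims <- sample(2:max_dim, 3L, replace = TRUE)
  g <- array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
  g[stats::runif(prod(dims)) < p_na] <- NA_integer_
  # ensure at least two voxels remain and levels start at 1
  if (sum(!is.na(g)) < 2L) g[1:2] <- c(1L, ng)
  g
}

# matrices can differ in trailing all-zero columns (max run/zone/dependence)
trim_zero_cols <- function(P) {
  storage.mode(P) <- "double"
  nz <- which(colSums(P) > 0)
  if (length(nz) == 0L) return(P[, 0, drop = FALSE])
  P[, seq_len(max(nz)), drop = FALSE]
}
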