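# shared helpers for texture-matrix construction

# the 13 unique 3-D direction offsets (slice, row, col), up to sign
DIRECTIONS_13 <- rbind(
  c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
  c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
  c(1, 1, 0), c(1, -1, 0),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# neighbor values at offset d: out[i] = g[i + d], NA outside the grid
shift_grid <- function(g, d) {
  dims <- dim(g)
  out <- array(NA_integer_, dim = dims)
  rng <- function(n, dd) {
    start <- max(1L, 1L - dd); end <- min(n, n - dd)
    if (end < start) integer(0) else start:end
  }
  tk <- rng(dims[1], d[1]); tr <- rng(dims[2], d[2]); tc <- rng(dims[3], d[3])
  out[tk, tr, tc] <- g[tk + d[1], tr + d[2], tc + d[3]]
  out
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

feature_rows <- function(family, values) {
  data.frame(family = family, name = names(values),
             value = as.numeric(values), stringsAsFactors = FALSE)
}

# average feature vectors over directions, dropping NULL (empty) directions
.average_directions <- function(per_dir) {
  per_dir <- Filter(Negate(is.null), per_dir)
  if (length(per_dir) == 0L) return(NULL)
  Reduce(`+`, per_dir) / length(per_dir)
}
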