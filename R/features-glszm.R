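#' Gray-level size-zone matrix features (16)
#'
#' Zones are 26-connected components of equal gray level; the size-zone
#' matrix counts zones by (level, size). A single matrix describes the whole
#' region (no direction averaging).
#'
#' @param d a `discretized_region`
#' @return data.frame with columns `family`, `name`, `value` (16 rows)
#' @export
glszm_features <- function(d) {
  P <- glszm_matrix(d$grid, d$ng)
  feature_rows("glszm", .rl_stats(P, length(d$levels), .glszm_names))
}

#' Size-zone count matrix
#'
#' @inheritParams glcm_matrix
#' @return `ng` x `max_zone_size` count matrix
#' @export
glszm_matrix <- function(grid, ng) {
  zones <- .label_zones(grid)
  sizes <- tabulate(zones$membership)
  levels <- zones$level
  ns <- max(sizes)
  matrix(tabulate((sizes - 1L) * ng + levels, ng * ns), ng, ns)
}

# 26-connected same-level components; returns per-zone level and a
# membership vector over masked voxels
.label_zones <- function(grid) {
  dims <- dim(grid)
  n <- sum(!is.na(grid))
  node <- array(NA_integer_, dims)
  node[!is.na(grid)] <- seq_len(n)
  edges <- list()
  for (di in seq_len(nrow(DIRECTIONS_13))) {
    off <- DIRECTIONS_13[di, ]
    nb_lvl <- shift_grid(grid, off)
    nb_node <- shift_grid(node, off)
    ok <- !is.na(grid) & !is.na(nb_lvl) & grid == nb_lvl
    if (any(ok))
      edges[[length(edges) + 1L]] <- cbind(node[ok], nb_node[ok])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  membership <- comp$membership
  first_of_zone <- match(seq_len(comp$no), membership)
  list(membership = membership,
       level = grid[!is.na(grid)][first_of_zone],
       n_zones = comp$no)
}
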