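# Independent oracles used across the test files. These deliberately use
# naive algorithms (recursion-free flood fill, exhaustive enumeration) so
# they share no code with the implementation they check.

# largest connected component by repeated neighbourhood expansion on the
# occupancy grid
oracle_largest_cluster <- function(occupancy, connectivity) {
  coords <- which(occupancy, arr.ind = TRUE)  # (row, col), 1-based
  n <- nrow(coords)
  if (n == 0L) return(0L)
  adjacent <- function(a, b) {
    dr <- abs(a[1L] - b[1L]); dc <- abs(a[2L] - b[2L])
    if (connectivity == 4L) dr + dc == 1L else max(dr, dc) == 1L
  }
  label <- rep(0L, n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (label[i] > 0L) next
    next_label <- next_label + 1L
    frontier <- i
    label[i] <- next_label
    while (length(frontier)) {
      new_frontier <- integer(0)
      for (f in frontier) {
        for (j in seq_len(n)) {
          if (label[j] == 0L && adjacent(coords[f, ], coords[j, ])) {
            label[j] <- next_label
            new_frontier <- c(new_frontier, j)
          }
        }
      }
      frontier <- new_frontier
    }
  }
  max(tabulate(label))
}

# exhaustive count of unordered site pairs at a given separation
oracle_site_pairs <- function(n_rows, n_cols, l, mode) {
  sites <- expand.grid(x = seq_len(n_cols) - 1L, y = seq_len(n_rows) - 1L)
  n <- nrow(sites)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sep <- abs(sites$y[i] - sites$y[j])
      if (mode == "XY") sep <- sep + abs(sites$x[i] - sites$x[j])
      if (sep == l) count <- count + 1L
    }
  }
  count
}

# random lattice state for property tests
random_state <- function(config = lattice_config(), n_cells = NULL) {
  n_sites <- config$n_rows * config$n_cols
  if (is.null(n_cells)) n_cells <- sample.int(n_sites, 1L)
  sites <- sample.int(n_sites, n_cells) - 1L
  lattice_state(cbind(sites %% config$n_cols, sites %/% config$n_cols),
                config)
}

# is point p inside (or on) the convex hull of the 2-column matrix pts?
inside_convex_hull <- function(p, pts) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) return(FALSE)
  sgn <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
  }, numeric(1))
  all(sgn <= 0) || all(sgn >= 0)
}

scratch_design <- function(n_initial = 24L, n_replicates = 10L)
  design_spec(seeded_rows = 6L, n_initial = n_initial,
              n_replicates = n_replicates)

growth_design <- function(n_initial = 24L, n_replicates = 10L)
  design_spec(seeded_rows = 24L, n_initial = n_initial,
              n_replicates = n_replicates)

true_params <- function() model_params(0.25, 0.0025)
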