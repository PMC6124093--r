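#' Summary statistic identifiers
#'
#' The thirteen summary statistics of a replicate. All are evaluated on the
#' final-time cell positions except the two trajectory statistics (`disp`,
#' `tort`), which use the tracked-cell trajectories. The correlation
#' statistics are vectors over separations `l = 1..24`; all others are
#' scalars.
#'
#' * `N` - final cell number
#' * `kappa4`, `kappa8` - size of the largest 4- / 8-connected cluster
#' * `Q2`, `Q4`, `Q8` - binning variance with quadrat width 2 / 4 / 8
#' * `disp` - mean total Manhattan displacement of the tracked cells
#' * `tort` - mean Manhattan tortuosity of the tracked trajectories
#' * `gyr` - smallest eigenvalue of the gyration tensor
#' * `Cxy`, `Cxy_hat` - (normalized) two-dimensional pair correlation
#' * `Cy`, `Cy_hat` - (normalized) one-dimensional (vertical) pair correlation
#'
#' @return Character vector of the 13 statistic ids.
#' @export
summary_statistic_ids <- function() {
  c("N", "kappa4", "kappa8", "Q2", "Q4", "Q8", "disp", "tort", "gyr",
    "Cxy", "Cxy_hat", "Cy", "Cy_hat")
}

# maximum separation retained by the pair-correlation statistics; fixed by
# the number of rows of the default lattice
CORR_MAX_L <- 24L

#' Final cell number
#'
#' @param state A `lattice_state`.
#' @return The number of cells, `N`.
#' @export
cell_count <- function(state) nrow(state$cells)

#' Size of the largest connected cluster
#'
#' Cells that are orthogonally adjacent (`connectivity = 4`) or orthogonally
#' or diagonally adjacent (`connectivity = 8`) belong to one cluster; the
#' statistic is the cell count of the largest cluster. An empty lattice gives
#' 0 by convention.
#'
#' @param state A `lattice_state`.
#' @param connectivity 4 or 8.
#' @return Largest cluster size.
#' @export
largest_cluster <- function(state, connectivity = 4L) {
  cpp_largest_cluster(state$cells, state$config$n_rows, state$config$n_cols,
                      as.integer(connectivity))
}

#' Binning variance
#'
#' Partitions the lattice into non-overlapping `bin_width x bin_width`
#' quadrats (`B_k = R C / k^2` of them) and returns the sum of squared
#' deviations of the quadrat cell counts from their mean `N / B_k`.
#'
#' @param state A `lattice_state`.
#' @param bin_width Quadrat width `k`; must divide both lattice dimensions.
#' @return The binning variance `Q_k`.
#' @export
binning_variance <- function(state, bin_width) {
  R <- state$config$n_rows; C <- state$config$n_cols
  k <- as.integer(bin_width)
  if (R %% k != 0L || C %% k != 0L)
    stop("bin_width must divide both lattice dimensions", call. = FALSE)
  stat_binvar(state$cells[, 1L], state$cells[, 2L], R, C, k)
}

stat_binvar <- function(xs, ys, R, C, k) {
  n_bins <- (R %/% k) * (C %/% k)
  n <- length(xs)
  if (n == 0L) return(0)
  b <- (xs %/% k) + (C %/% k) * (ys %/% k) + 1L
  counts <- tabulate(b, nbins = n_bins)
  sum((counts - n / n_bins)^2)
}

# trajectories: integer array n_rec x 2 x n_tracked (0-based coordinates)
check_traj <- function(trajectories) {
  stopifnot(is.array(trajectories), length(dim(trajectories)) == 3L,
            dim(trajectories)[2L] == 2L)
  if (dim(trajectories)[1L] < 2L)
    stop("trajectories need at least two recorded positions", call. = FALSE)
}

#' Mean total Manhattan displacement of the tracked cells
#'
#' For each tracked cell, sums the L1 distances between consecutive recorded
#' positions; returns the mean over tracked cells, in lattice units.
#'
#' @param trajectories Integer array `n_records x 2 x n_tracked`, as stored
#'   in a `replicate_result`.
#' @return The displacement statistic.
#' @export
manhattan_displacement <- function(trajectories) {
  check_traj(trajectories)
  n_rec <- dim(trajectories)[1L]
  sum(abs(trajectories[-1L, , , drop = FALSE] -
            trajectories[-n_rec, , , drop = FALSE])) /
    dim(trajectories)[3L]
}

#' Mean Manhattan tortuosity of the tracked trajectories
#'
#' Per tracked cell, the ratio of the summed L1 increments between recorded
#' frames to the net L1 displacement between the first and last frame;
#' returns the mean over tracked cells. Cells with zero net displacement make
#' the ratio undefined and are excluded from the mean; if every tracked cell
#' is degenerate the statistic is `NA` (and any ABC sample whose distance
#' uses it is rejected).
#'
#' @inheritParams manhattan_displacement
#' @return The tortuosity statistic (`>= 1` when defined), or `NA`.
#' @export
tortuosity <- function(trajectories) {
  check_traj(trajectories)
  stat_tortuosity(trajectories)
}

stat_tortuosity <- function(trajectories) {
  n_rec <- dim(trajectories)[1L]
  path <- colSums(abs(matrix(trajectories[-1L, , , drop = FALSE] -
                               trajectories[-n_rec, , , drop = FALSE],
                             nrow = n_rec - 1L)))
  path <- path[seq(1L, length(path), by = 2L)] +
    path[seq(2L, length(path), by = 2L)]
  net <- abs(trajectories[n_rec, 1L, ] - trajectories[1L, 1L, ]) +
    abs(trajectories[n_rec, 2L, ] - trajectories[1L, 2L, ])
  ok <- net > 0
  if (!any(ok)) return(NA_real_)
  mean(path[ok] / net[ok])
}

#' Smallest eigenvalue of the gyration tensor
#'
#' Builds the 2x2 gyration tensor from signed pairwise coordinate
#' differences, `G_ab = (1/N^2) * sum_{i<j} d_a(i,j) d_b(i,j)`, and returns
#' its smaller eigenvalue, which quantifies the spread of the colony along
#' its minor principal axis. Returns 0 when fewer than 2 cells are present.
#'
#' @param state A `lattice_state`.
#' @param absolute Use absolute instead of signed coordinate differences in
#'   the off-diagonal entries (sensitivity switch; the diagonal is
#'   unaffected). Default `FALSE`.
#' @return The smaller eigenvalue (non-negative for signed differences).
#' @export
gyration_min_eigenvalue <- function(state, absolute = FALSE) {
  stat_gyration(state$cells[, 1L], state$cells[, 2L], absolute)
}

stat_gyration <- function(xs, ys, absolute = FALSE) {
  n <- length(xs)
  if (n < 2L) return(0)
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  # sum_{i<j} (xi - xj)(yi - yj) = n * sum(x y) - sum(x) sum(y)
  g11 <- (n * sum(xs * xs) - sum(xs)^2) / n^2
  g22 <- (n * sum(ys * ys) - sum(ys)^2) / n^2
  if (absolute) {
    dx <- abs(outer(xs, xs, "-")); dy <- abs(outer(ys, ys, "-"))
    g12 <- sum(dx[upper.tri(dx)] * dy[upper.tri(dy)]) / n^2
  } else {
    g12 <- (n * sum(xs * ys) - sum(xs) * sum(ys)) / n^2
  }
  (g11 + g22) / 2 - sqrt(((g11 - g22) / 2)^2 + g12^2)
}

#' Pair correlation function of cell positions
#'
#' Counts unordered pairs of cells at each separation `l = 1..24`. Mode `"Y"`
#' uses the vertical separation `|dY|` only (sensitive to the vertical
#' heterogeneity of the seeding geometry); mode `"XY"` uses the Manhattan
#' separation `|dX| + |dY|`. Pairs at separation 0 or beyond 24 are not
#' recorded.
#'
#' @param state A `lattice_state`.
#' @param mode `"Y"` or `"XY"`.
#' @return Integer vector of length 24, pair counts per separation.
#' @export
pair_correlation <- function(state, mode = c("XY", "Y")) {
  mode <- match.arg(mode)
  if (mode == "Y") stat_corr_y(state$cells) else stat_corr_xy(state$cells)
}

stat_corr_y <- function(cells) {
  as.numeric(cpp_pair_counts(cells, CORR_MAX_L, FALSE))
}

stat_corr_xy <- function(cells) {
  as.numeric(cpp_pair_counts(cells, CORR_MAX_L, TRUE))
}

# number of unordered site pairs at each separation l = 1..max_l; depends
# only on the lattice dimensions, so callers cache it across replicates
site_pair_counts <- function(mode, config, max_l = CORR_MAX_L) {
  R <- config$n_rows; C <- config$n_cols
  vapply(seq_len(max_l), function(li) {
    if (mode == "Y") {
      C^2 * max(R - li, 0)
    } else {
      s <- C * max(R - li, 0) + max(C - li, 0) * R
      if (li > 1L) {
        j <- seq_len(li - 1L)
        s <- s + 2 * sum(pmax(C - j, 0) * pmax(R - (li - j), 0))
      }
      s
    }
  }, numeric(1))
}

#' Expected pair count at a given separation under random placement
#'
#' Closed-form expected number of unordered cell pairs at separation `l` for
#' `N` cells placed uniformly at random on the lattice: the number of site
#' pairs at that separation times `rho * rhobar` with `rho = N / (C R)` and
#' `rhobar = (N - 1) / (C R - 1)`. For mode `"Y"` the site-pair count is
#' `C^2 (R - l)`; for mode `"XY"` it is the sum over splits of `l` into a
#' horizontal and a vertical offset. Offset factors are floored at zero so
#' the count is exact on lattices narrower than `l`.
#'
#' @param l Separation(s), `1 <= l`.
#' @param mode `"Y"` or `"XY"`.
#' @param n_cells Cell count `N >= 2`.
#' @param config A [lattice_config()].
#' @return Expected pair count(s) `q(l)`.
#' @export
expected_pair_count <- function(l, mode = c("XY", "Y"), n_cells,
                                config = lattice_config()) {
  mode <- match.arg(mode)
  stopifnot(all(l >= 1), n_cells >= 2)
  R <- config$n_rows; C <- config$n_cols
  rho <- n_cells / (C * R)
  rhobar <- (n_cells - 1) / (C * R - 1)
  # split l = j + (l - j) into horizontal and vertical offsets; the two
  # diagonal orientations give the factor 2 for mixed splits
  site_pair_counts(mode, config, max(l))[l] * rho * rhobar
}

#' Normalize a pair correlation function
#'
#' Elementwise ratio of observed to expected pair counts. Separations with
#' zero expected count (possible on narrow observation windows, and at
#' `l = R` for mode `"Y"`) are returned as `NA` and excluded from ABC
#' distances.
#'
#' @param raw Pair counts, as returned by [pair_correlation()].
#' @param expected Expected counts, as returned by [expected_pair_count()].
#' @return Numeric vector `raw / expected`, `NA` where `expected == 0`.
#' @export
normalize_correlation <- function(raw, expected) {
  stopifnot(length(raw) == length(expected))
  out <- ifelse(expected > 0, raw / expected, NA_real_)
  as.numeric(out)
}

# site-pair counts for both correlation modes, cached by the ABC loops
corr_norm_factors <- function(config) {
  list(y = site_pair_counts("Y", config),
       xy = site_pair_counts("XY", config))
}

# fast path shared by the public API and the ABC loops: computes the named
# statistics from the cell coordinate matrix and the trajectory array
compute_stats_raw <- function(cells, traj, config, stat_ids, norm = NULL) {
  n <- nrow(cells)
  R <- config$n_rows; C <- config$n_cols
  if (is.null(norm)) norm <- corr_norm_factors(config)
  rr <- max(n, 2)
  rho2 <- (rr / (C * R)) * ((rr - 1) / (C * R - 1))
  out <- vector("list", length(stat_ids))
  names(out) <- stat_ids
  for (id in stat_ids) {
    out[[id]] <- switch(id,
      N = n,
      kappa4 = cpp_largest_cluster(cells, R, C, 4L),
      kappa8 = cpp_largest_cluster(cells, R, C, 8L),
      Q2 = stat_binvar(cells[, 1L], cells[, 2L], R, C, 2L),
      Q4 = stat_binvar(cells[, 1L], cells[, 2L], R, C, 4L),
      Q8 = stat_binvar(cells[, 1L], cells[, 2L], R, C, 8L),
      disp = sum(abs(traj[-1L, , , drop = FALSE] -
                       traj[-dim(traj)[1L], , , drop = FALSE])) /
        dim(traj)[3L],
      tort = stat_tortuosity(traj),
      gyr = stat_gyration(cells[, 1L], cells[, 2L]),
      Cxy = stat_corr_xy(cells),
      Cxy_hat = normalize_correlation(stat_corr_xy(cells), norm$xy * rho2),
      Cy = stat_corr_y(cells),
      Cy_hat = normalize_correlation(stat_corr_y(cells), norm$y * rho2),
      stop("unknown statistic id: ", id))
  }
  out
}

#' Compute all (or selected) summary statistics of a replicate
#'
#' Trajectory statistics (`disp`, `tort`) are computed from the tracked
#' trajectories; all others from the final-time cell positions.
#'
#' @param replicate A `replicate_result`, as returned by [run_replicate()].
#' @param stat_ids Statistics to compute; default all 13.
#' @return Named list of statistic values (scalars, or length-24 vectors for
#'   the correlation statistics).
#' @examples
#' set.seed(2)
#' rep1 <- run_replicate(design_spec(seeded_rows = 6, n_initial = 24),
#'                       model_params(0.25, 0.0025))
#' s <- compute_statistic_set(rep1)
#' s$N; s$Cy[1:6]
#' @export
compute_statistic_set <- function(replicate,
                                  stat_ids = summary_statistic_ids()) {
  st <- replicate$final_state
  compute_stats_raw(st$cells, replicate$trajectories, st$config, stat_ids)
}

#' Summary statistics of a whole dataset as a tidy table
#'
#' @param dataset An `observed_dataset`.
#' @param stat_ids Statistics to compute; default all 13.
#' @return A data frame with columns `replicate`, `statistic_id`, `l`,
#'   `value`.
#' @export
compute_dataset_statistics <- function(dataset,
                                       stat_ids = summary_statistic_ids()) {
  rows <- lapply(seq_along(dataset$replicates), function(m) {
    s <- compute_statistic_set(dataset$replicates[[m]], stat_ids)
    do.call(rbind, lapply(names(s), function(id) {
      data.frame(replicate = m, statistic_id = id,
                 l = seq_along(s[[id]]), value = as.numeric(s[[id]]))
    }))
  })
  do.call(rbind, rows)
}
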