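#' Model parameters
#'
#' Per-time-step movement and proliferation probabilities of the lattice
#' exclusion process. During each time step of duration `tau`, every cell (on
#' average) draws a uniform number u: for u below `p_move` it attempts a move
#' into one of the four orthogonally adjacent sites, for u between `p_move`
#' and `p_move + p_prolif` it attempts to place a daughter there;
#' attempts onto occupied sites or off the lattice are aborted.
#'
#' @param p_move Per-step movement probability, in `[0, 1]`.
#' @param p_prolif Per-step proliferation probability, in `[0, 1]`.
#' @return An object of class `model_params`.
#' @examples
#' model_params(0.25, 0.0025)
#' @export
model_params <- function(p_move, p_prolif) {
  stopifnot(is.numeric(p_move), length(p_move) == 1L,
            is.numeric(p_prolif), length(p_prolif) == 1L)
  if (p_move < 0 || p_prolif < 0 || p_move + p_prolif > 1)
    stop("need p_move >= 0, p_prolif >= 0 and p_move + p_prolif <= 1",
         call. = FALSE)
  structure(list(p_move = p_move, p_prolif = p_prolif),
            class = "model_params")
}

#' Lattice configuration
#'
#' Geometry and time discretization of the simulation lattice. Defaults match
#' a typical microscopy field of view: 24 rows by 32 columns of square sites
#' of side 18.75 micrometres (about one cell diameter), with time steps of
#' 1/24 h (2.5 min).
#'
#' @param n_rows,n_cols Lattice dimensions (rows `R`, columns `C`).
#' @param site_length Site side length in micrometres.
#' @param step_duration Duration of one simulation step, in hours.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(n_rows = 24L, n_cols = 32L, site_length = 18.75,
                           step_duration = 1 / 24) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, site_length > 0, step_duration > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, site_length = site_length,
                 step_duration = step_duration),
            class = "lattice_config")
}

#' Experimental design specification
#'
#' Describes an in silico assay: how many cells are seeded, into how many
#' rows (counted from row 0, the seeded edge), for how long the colony is
#' observed, and how trajectories of tracked founder cells are recorded.
#' Seeding all rows emulates a growth-to-confluence assay; seeding a narrow
#' band of rows emulates the dense front left by a scratch assay.
#'
#' @param seeded_rows Number of rows (from the seeded edge) into which the
#'   initial cells are placed uniformly at random.
#' @param n_initial Initial cell number `N(0)`.
#' @param duration Assay duration `T`, in hours.
#' @param record_interval Number of simulation steps between recorded
#'   trajectory positions (8 steps of 2.5 min = 20-minute frames).
#' @param n_tracked Number of founder cells whose trajectories are recorded.
#' @param n_replicates Number of independent replicates `M` per dataset.
#' @return An object of class `design_spec`.
#' @examples
#' scratch <- design_spec(seeded_rows = 6, n_initial = 24)
#' growth  <- design_spec(seeded_rows = 24, n_initial = 24)
#' @export
design_spec <- function(seeded_rows = 24L, n_initial = 24L, duration = 12,
                        record_interval = 8L, n_tracked = 5L,
                        n_replicates = 10L) {
  seeded_rows <- as.integer(seeded_rows)
  n_initial <- as.integer(n_initial)
  record_interval <- as.integer(record_interval)
  n_tracked <- as.integer(n_tracked)
  n_replicates <- as.integer(n_replicates)
  stopifnot(seeded_rows >= 1L, n_initial >= 1L, duration > 0,
            record_interval >= 1L, n_tracked >= 0L, n_replicates >= 1L)
  if (n_tracked > n_initial)
    stop("n_tracked cannot exceed n_initial", call. = FALSE)
  structure(list(seeded_rows = seeded_rows, n_initial = n_initial,
                 duration = duration, record_interval = record_interval,
                 n_tracked = n_tracked, n_replicates = n_replicates),
            class = "design_spec")
}

# number of steps implied by a design on a config; must be an integer
# multiple of the record interval
n_steps_for <- function(design, config) {
  n_steps <- design$duration / config$step_duration
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration must be an integer number of time steps", call. = FALSE)
  n_steps <- as.integer(round(n_steps))
  if (design$n_tracked > 0L && n_steps %% design$record_interval != 0L)
    stop("record_interval must divide the number of steps", call. = FALSE)
  n_steps
}

new_lattice_state <- function(cells, config, tracked = integer(0),
                              step_index = 0L) {
  occupancy <- matrix(FALSE, config$n_rows, config$n_cols)
  if (nrow(cells) > 0)
    occupancy[cbind(cells[, 2L] + 1L, cells[, 1L] + 1L)] <- TRUE
  structure(list(occupancy = occupancy, cells = cells, tracked = tracked,
                 step_index = as.integer(step_index), config = config),
            class = "lattice_state")
}

#' Construct a lattice state from cell coordinates
#'
#' @param cells Integer matrix with columns `(x_col, y_row)`, 0-based.
#' @param config A [lattice_config()].
#' @param tracked Integer indices (into rows of `cells`) of tracked cells.
#' @param step_index Simulation step the state corresponds to.
#' @return An object of class `lattice_state` with fields `occupancy`
#'   (logical `n_rows x n_cols` matrix), `cells`, `tracked` and `step_index`.
#' @export
lattice_state <- function(cells, config = lattice_config(),
                          tracked = integer(0), step_index = 0L) {
  cells <- matrix(as.integer(cells), ncol = 2L,
                  dimnames = list(NULL, c("x_col", "y_row")))
  if (nrow(cells) > 0) {
    if (any(cells[, 1L] < 0L) || any(cells[, 1L] >= config$n_cols) ||
        any(cells[, 2L] < 0L) || any(cells[, 2L] >= config$n_rows))
      stop("cell coordinates out of bounds", call. = FALSE)
    if (anyDuplicated(cells))
      stop("duplicate cell coordinates violate volume exclusion",
           call. = FALSE)
  }
  new_lattice_state(cells, config, tracked, step_index)
}

#' Seed the initial lattice
#'
#' Places `n_initial` cells uniformly at random over distinct sites of the
#' first `seeded_rows` rows of the lattice, and flags `n_tracked` of them
#' (chosen uniformly at random) for trajectory recording.
#'
#' @param design A [design_spec()].
#' @param config A [lattice_config()].
#' @return A `lattice_state` at step 0.
#' @examples
#' set.seed(1)
#' st <- initialize_lattice(design_spec(seeded_rows = 6, n_initial = 24))
#' sum(st$occupancy)
#' @export
initialize_lattice <- function(design, config = lattice_config()) {
  if (design$n_initial > design$seeded_rows * config$n_cols)
    stop("infeasible placement: n_initial exceeds the number of seeded sites",
         call. = FALSE)
  init <- cpp_init_cells(config$n_rows, config$n_cols, design$seeded_rows,
                         design$n_initial, design$n_tracked)
  cells <- init$cells
  colnames(cells) <- c("x_col", "y_row")
  new_lattice_state(cells, config, init$tracked, 0L)
}

#' Advance the exclusion process by one time step
#'
#' Performs one step of the lattice exclusion process: `N(t)` cell selections
#' with replacement from the population present at the start of the step; each
#' selected cell attempts a movement (probability `p_move`) or proliferation
#' (probability `p_prolif`) event into a uniformly chosen orthogonal
#' neighbour, aborted if the target site is occupied or off the lattice.
#' Daughters born within the step cannot be selected until the next step.
#'
#' @param state A `lattice_state`.
#' @param params A [model_params()].
#' @return The updated `lattice_state` (with `step_index` incremented).
#' @export
simulation_step <- function(state, params) {
  res <- cpp_simulate(state$cells, state$config$n_rows, state$config$n_cols,
                      params$p_move, params$p_prolif, 1L,
                      integer(0), 0L)
  cells <- res$cells
  colnames(cells) <- c("x_col", "y_row")
  new_lattice_state(cells, state$config, state$tracked, state$step_index + 1L)
}

#' Run a single replicate of the assay
#'
#' Seeds the lattice per `design`, runs `duration / step_duration` steps and
#' records tracked-cell positions every `record_interval` steps, including
#' step 0 and the final step.
#'
#' @param design A [design_spec()].
#' @param params A [model_params()].
#' @param config A [lattice_config()].
#' @param seed Optional integer seed set before the replicate runs (recorded
#'   in the result).
#' @return An object of class `replicate_result` with fields `final_state`
#'   (a `lattice_state`), `trajectories` (an integer array of dimension
#'   `n_records x 2 x n_tracked`; coordinate slices `x`, `y`, 0-based) and
#'   `seed`.
#' @examples
#' set.seed(7)
#' rep1 <- run_replicate(design_spec(seeded_rows = 6, n_initial = 24),
#'                       model_params(0.25, 0.0025))
#' cell_count(rep1$final_state)
#' @export
run_replicate <- function(design, params, config = lattice_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_steps <- n_steps_for(design, config)
  init <- cpp_init_cells(config$n_rows, config$n_cols, design$seeded_rows,
                         design$n_initial, design$n_tracked)
  res <- cpp_simulate(init$cells, config$n_rows, config$n_cols,
                      params$p_move, params$p_prolif, n_steps,
                      init$tracked, design$record_interval)
  cells <- res$cells
  colnames(cells) <- c("x_col", "y_row")
  traj <- res$traj
  if (design$n_tracked > 0L)
    dimnames(traj) <- list(NULL, c("x", "y"), NULL)
  structure(list(final_state = new_lattice_state(cells, config, init$tracked,
                                                 n_steps),
                 trajectories = traj,
                 design = design, params = params,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "replicate_result")
}

#' Generate a replicated in silico dataset
#'
#' Runs `n_replicates` independent replicates of the assay. Replicate seeds
#' are spawned deterministically from the master seed (by drawing
#' `n_replicates` integers from the seeded stream), so a dataset is exactly
#' reproducible from `(design, params, config, seed)`.
#'
#' @inheritParams run_replicate
#' @param seed Master seed for the dataset.
#' @return An object of class `observed_dataset`: a list with `replicates`
#'   (list of `replicate_result`), `params_true`, `design`, `config`, `seed`.
#' @examples
#' obs <- generate_observed_dataset(design_spec(seeded_rows = 6, n_initial = 24),
#'                                  model_params(0.25, 0.0025), seed = 11)
#' length(obs$replicates)
#' @export
generate_observed_dataset <- function(design, params,
                                      config = lattice_config(), seed = 1L) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, design$n_replicates)
  replicates <- lapply(sub_seeds, function(s)
    run_replicate(design, params, config, seed = s))
  structure(list(replicates = replicates, params_true = params,
                 design = design, config = config, seed = as.integer(seed)),
            class = "observed_dataset")
}

#' Continuum-limit transport rates
#'
#' Maps the per-step probabilities onto the classical diffusion coefficient
#' `D = p_move * delta^2 / (4 tau)` (micrometres squared per hour) and the
#' proliferation rate `lambda = p_prolif / tau` (per hour) of the
#' corresponding continuum limit.
#'
#' @param params A [model_params()].
#' @param config A [lattice_config()].
#' @return Named numeric vector with elements `diffusivity` and
#'   `prolif_rate`.
#' @examples
#' continuum_rates(model_params(0.25, 0.0025), lattice_config())
#' @export
continuum_rates <- function(params, config = lattice_config()) {
  c(diffusivity = params$p_move * config$site_length^2 /
      (4 * config$step_duration),
    prolif_rate = params$p_prolif / config$step_duration)
}

#' Restrict a state to an observation window
#'
#' Keeps only the cells inside the first `n_rows` rows and `n_cols` columns,
#' emulating data collection on an image window smaller than the physical
#' dish (used to check insensitivity of results to the domain size).
#'
#' @param state A `lattice_state`.
#' @param n_rows,n_cols Window dimensions; default the full lattice.
#' @return A `lattice_state` on the window lattice.
#' @export
observation_window <- function(state, n_rows = state$config$n_rows,
                               n_cols = state$config$n_cols) {
  keep <- state$cells[, 1L] < n_cols & state$cells[, 2L] < n_rows
  cfg <- state$config
  cfg$n_rows <- as.integer(n_rows)
  cfg$n_cols <- as.integer(n_cols)
  new_lattice_state(state$cells[keep, , drop = FALSE], cfg,
                    integer(0), state$step_index)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat("<lattice_state> ", nrow(x$cells), " cells on ",
      x$config$n_rows, "x", x$config$n_cols, " lattice, step ",
      x$step_index, "\n", sep = "")
  invisible(x)
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat("<observed_dataset> M =", length(x$replicates), "replicates;",
      "design:", x$design$n_initial, "cells over", x$design$seeded_rows,
      "rows;", "params: p_move =", x$params_true$p_move,
      "p_prolif =", x$params_true$p_prolif, "\n")
  invisible(x)
}
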