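#' Default run configuration
#'
#' Collects every tunable setting of the pipeline with its default value:
#' lattice geometry, design, generating parameters, prior box, ABC and
#' data-cloning settings. Coordinates in all outputs are 0-based
#' `(column, row)` with row 0 at the seeded edge.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    n_rows = 24L, n_cols = 32L, site_length = 18.75, step_duration = 1 / 24,
    seeded_rows = 24L, n_initial = 24L, duration = 12,
    record_interval = 8L, n_tracked = 5L, n_replicates = 10L,
    p_move = 0.25, p_prolif = 0.0025,
    pm_prior = c(0, 0.99), pp_prior = c(0, 0.01),
    K = 10000L, accept_frac = 0.01, n_grid = 512L,
    proposal_scale = c(0.02, 2e-4),
    seed = 1L),
    class = "run_config")
}

#' Parse a YAML run configuration
#'
#' Reads a YAML file of settings, fills unset fields with the defaults of
#' [default_run_config()], rejects unknown keys, and validates the values
#' (lattice dimensions, probability bounds, prior box).
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return A validated `run_config`.
#' @export
parse_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (length(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(user)) {
      v <- user[[k]]
      if (is.integer(cfg[[k]])) v <- as.integer(v)
      cfg[[k]] <- v
    }
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  # the constructors carry the invariants; field names surface in errors
  check <- function(expr, field) {
    ok <- tryCatch({expr; TRUE}, error = function(e) e)
    if (!isTRUE(ok))
      stop("invalid configuration field '", field, "': ",
           conditionMessage(ok), call. = FALSE)
  }
  check(lattice_config(cfg$n_rows, cfg$n_cols, cfg$site_length,
                       cfg$step_duration), "n_rows/n_cols/site_length/step_duration")
  check(design_spec(cfg$seeded_rows, cfg$n_initial, cfg$duration,
                    cfg$record_interval, cfg$n_tracked, cfg$n_replicates),
        "seeded_rows/n_initial/duration/record_interval/n_tracked/n_replicates")
  check(model_params(cfg$p_move, cfg$p_prolif), "p_move/p_prolif")
  check(prior_spec(cfg$pm_prior, cfg$pp_prior), "pm_prior/pp_prior")
  if (cfg$seeded_rows > cfg$n_rows)
    stop("invalid configuration field 'seeded_rows': exceeds n_rows",
         call. = FALSE)
  invisible(cfg)
}

#' Write a run configuration to YAML
#'
#' Round-trips losslessly through [parse_config()].
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17L)
  invisible(path)
}

#' Write an observed dataset to plain-text files
#'
#' Writes `positions.csv` (`replicate, time_h, cell_id, x_col, y_row,
#' tracked`), `trajectories.csv` (`replicate, cell_id, step, x_col, y_row`)
#' and `metadata.json` (parameters, design, lattice configuration, master
#' seed, replicate seeds) into `dir`. Coordinates are 0-based
#' `(column, row)`.
#'
#' @param dataset An `observed_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- do.call(rbind, lapply(seq_along(dataset$replicates), function(m) {
    r <- dataset$replicates[[m]]
    st <- r$final_state
    n <- nrow(st$cells)
    data.frame(replicate = m,
               time_h = st$step_index * st$config$step_duration,
               cell_id = seq_len(n),
               x_col = st$cells[, 1L], y_row = st$cells[, 2L],
               tracked = as.integer(seq_len(n) %in% st$tracked))
  }))
  write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  trj <- do.call(rbind, lapply(seq_along(dataset$replicates), function(m) {
    r <- dataset$replicates[[m]]
    tr <- r$trajectories
    if (length(tr) == 0L) return(NULL)
    n_rec <- dim(tr)[1L]
    steps <- (seq_len(n_rec) - 1L) * r$design$record_interval
    do.call(rbind, lapply(seq_len(dim(tr)[3L]), function(t)
      data.frame(replicate = m, cell_id = r$final_state$tracked[t],
                 step = steps, x_col = tr[, 1L, t], y_row = tr[, 2L, t])))
  }))
  write.csv(trj, file.path(dir, "trajectories.csv"), row.names = FALSE)
  meta <- list(params = unclass(dataset$params_true),
               design = unclass(dataset$design),
               config = unclass(dataset$config),
               seed = dataset$seed,
               replicate_seeds = vapply(dataset$replicates, `[[`, 1L,
                                        "seed"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an observed dataset written by [write_dataset()]
#'
#' @param dir Directory containing `positions.csv`, `trajectories.csv` and
#'   `metadata.json`.
#' @return An `observed_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  config <- do.call(lattice_config, meta$config)
  design <- do.call(design_spec, meta$design)
  params <- do.call(model_params, meta$params)
  pos <- read.csv(file.path(dir, "positions.csv"))
  trj <- read.csv(file.path(dir, "trajectories.csv"))
  n_steps <- round(design$duration / config$step_duration)
  replicates <- lapply(seq_len(design$n_replicates), function(m) {
    pm <- pos[pos$replicate == m, ]
    cells <- cbind(x_col = pm$x_col, y_row = pm$y_row)
    tracked <- pm$cell_id[pm$tracked == 1L]
    tm <- trj[trj$replicate == m, ]
    traj <- integer(0)
    if (nrow(tm)) {
      ids <- unique(tm$cell_id)
      n_rec <- sum(tm$cell_id == ids[1L])
      traj <- array(NA_integer_, c(n_rec, 2L, length(ids)),
                    dimnames = list(NULL, c("x", "y"), NULL))
      for (t in seq_along(ids)) {
        tt <- tm[tm$cell_id == ids[t], ]
        tt <- tt[order(tt$step), ]
        traj[, 1L, t] <- tt$x_col
        traj[, 2L, t] <- tt$y_row
      }
      tracked <- ids
    }
    structure(list(final_state = lattice_state(cells, config, tracked,
                                               n_steps),
                   trajectories = traj, design = design, params = params,
                   seed = meta$replicate_seeds[m]),
              class = "replicate_result")
  })
  structure(list(replicates = replicates, params_true = params,
                 design = design, config = config, seed = meta$seed),
            class = "observed_dataset")
}

#' Write accepted ABC samples to CSV
#'
#' Columns: `pm`, `pp`, adjusted values, the combined distance and the
#' per-statistic distances of each accepted sample.
#'
#' @param fit An `abc_fit`.
#' @param path Output CSV path.
#' @export
write_accepted <- function(fit, path) {
  df <- data.frame(pm = fit$theta[, "pm"], pp = fit$theta[, "pp"],
                   pm_adjusted = fit$theta_adj[, "pm"],
                   pp_adjusted = fit$theta_adj[, "pp"],
                   combined_distance = fit$distances[fit$accepted])
  for (id in fit$stat_ids)
    df[[paste0("d_", id)]] <- fit$per_statistic_distances[fit$accepted, id]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read accepted ABC samples written by [write_accepted()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_accepted <- function(path) read.csv(path)

#' Write a posterior grid as a delimited matrix plus axis metadata
#'
#' The density matrix goes to `<prefix>.tsv` (rows index `p_move`) and the
#' axes to `<prefix>.json`.
#'
#' @param grid A `posterior_grid`.
#' @param prefix Output path prefix.
#' @export
write_posterior_grid <- function(grid, prefix) {
  utils::write.table(format(grid$values, digits = 17),
                     paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(pm = grid$pm, pp = grid$pp,
                            cell_area = grid$cell_area,
                            pm_range = grid$prior$pm_range,
                            pp_range = grid$prior$pp_range),
                       paste0(prefix, ".json"), digits = NA)
  invisible(prefix)
}

#' Read a posterior grid written by [write_posterior_grid()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `posterior_grid`.
#' @export
read_posterior_grid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(vals) <- NULL
  structure(list(values = vals, pm = meta$pm, pp = meta$pp,
                 cell_area = meta$cell_area,
                 prior = prior_spec(meta$pm_range, meta$pp_range),
                 bandwidth = NULL),
            class = "posterior_grid")
}

#' Deterministic miniature test fixtures
#'
#' Builds a small, fully deterministic bundle exercising every summary
#' statistic including the degenerate branches: a mini dataset (8x8 lattice,
#' 6 cells over 4 rows, 24 steps, 3 replicates), a stationary replicate
#' whose tracked trajectories all have zero net displacement (triggering the
#' tortuosity degeneracy), and an empty lattice state (empty-cluster
#' convention).
#'
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @return List with elements `dataset`, `degenerate_replicate`,
#'   `empty_state`.
#' @export
make_fixtures <- function(seed = 1L) {
  config <- lattice_config(n_rows = 8L, n_cols = 8L)
  design <- design_spec(seeded_rows = 4L, n_initial = 6L, duration = 1,
                        record_interval = 8L, n_tracked = 3L,
                        n_replicates = 3L)
  dataset <- generate_observed_dataset(design, model_params(0.3, 0.02),
                                       config, seed = seed)
  set.seed(seed + 1L)
  degenerate <- run_replicate(design, model_params(0, 0), config)
  empty <- lattice_state(matrix(integer(0), 0L, 2L), config)
  list(dataset = dataset, degenerate_replicate = degenerate,
       empty_state = empty)
}
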