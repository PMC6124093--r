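test_that("parameter and design constructors enforce their invariants", {
  expect_error(model_params(0.8, 0.3), "p_move \\+ p_prolif")
  expect_error(model_params(-0.1, 0), "p_move")
  expect_error(design_spec(seeded_rows = 6, n_initial = 24, n_tracked = 30),
               "n_tracked")
  expect_error(initialize_lattice(design_spec(seeded_rows = 1,
                                              n_initial = 40)),
               "infeasible")
  expect_error(lattice_state(rbind(c(0, 0), c(0, 0))), "exclusion")
  expect_error(lattice_state(rbind(c(40, 0))), "bounds")
})

test_that("seeding places distinct cells uniformly in the seeded rows", {
  set.seed(101)
  d <- design_spec(seeded_rows = 6, n_initial = 24)
  st <- initialize_lattice(d)
  expect_equal(nrow(st$cells), 24L)
  expect_false(anyDuplicated(st$cells) > 0)
  expect_true(all(st$cells[, "y_row"] < 6))
  expect_equal(sum(st$occupancy), 24)
  expect_length(st$tracked, 5L)

  # a fully seeded block is forced by exclusion
  full <- initialize_lattice(design_spec(seeded_rows = 6,
                                         n_initial = 6 * 32))
  expect_true(all(full$occupancy[1:6, ]))
  expect_false(any(full$occupancy[7:24, ]))

  # per-site occupancy frequencies of a single seeded cell are uniform
  d1 <- design_spec(seeded_rows = 6, n_initial = 1, n_tracked = 0)
  counts <- matrix(0, 6, 32)
  for (i in 1:10000) {
    s <- initialize_lattice(d1)
    counts[s$cells[1, 2] + 1, s$cells[1, 1] + 1] <-
      counts[s$cells[1, 2] + 1, s$cells[1, 1] + 1] + 1
  }
  expect_gt(suppressWarnings(stats::chisq.test(as.vector(counts))$p.value),
            0.01)
})

test_that("one step obeys the event rules, exclusion and boundaries", {
  cfg <- lattice_config()
  st <- lattice_state(rbind(c(10, 10), c(11, 10)), cfg)

  # no event possible at zero rates
  expect_identical(simulation_step(st, model_params(0, 0))$cells, st$cells)

  # a completely full lattice is a fixed point for any parameters
  all_sites <- as.matrix(expand.grid(0:(cfg$n_cols - 1), 0:(cfg$n_rows - 1)))
  full <- lattice_state(all_sites, cfg)
  stepped <- simulation_step(full, model_params(0.9, 0.1))
  expect_equal(nrow(stepped$cells), nrow(all_sites))
  expect_true(all(stepped$occupancy))

  # a single interior cell at p_move = 1 lands on each neighbour with
  # frequency 1/4
  set.seed(202)
  p <- model_params(1, 0)
  moves <- integer(4)
  bad_step <- 0L
  single <- lattice_state(rbind(c(16, 12)), cfg)
  for (i in 1:40000) {
    after <- simulation_step(single, p)$cells
    dx <- unname(after[1, 1]) - 16L; dy <- unname(after[1, 2]) - 12L
    if (abs(dx) + abs(dy) != 1L) bad_step <- bad_step + 1L
    k <- if (dx == 1L) 1L else if (dx == -1L) 2L else if (dy == 1L) 3L else 4L
    moves[k] <- moves[k] + 1L
  }
  expect_equal(bad_step, 0L)  # exactly one lattice hop per step at p_move = 1
  # chi-square uniformity over the four directions
  expect_gt(stats::chisq.test(moves)$p.value, 1e-3)
})

test_that("population is monotone and exclusion always holds", {
  set.seed(303)
  p <- model_params(0.3, 0.05)
  st <- initialize_lattice(design_spec(seeded_rows = 6, n_initial = 40))
  violations <- 0L
  for (i in 1:60) {
    nxt <- simulation_step(st, p)
    n_before <- nrow(st$cells); n_after <- nrow(nxt$cells)
    if (n_after < n_before || n_after - n_before > n_before ||
        anyDuplicated(nxt$cells) > 0)
      violations <- violations + 1L
    st <- nxt
  }
  expect_equal(violations, 0L)
})

test_that("a replicate runs 288 steps and records 37 trajectory frames", {
  set.seed(404)
  rep1 <- run_replicate(scratch_design(), true_params())
  expect_equal(rep1$final_state$step_index, 288L)
  expect_equal(dim(rep1$trajectories), c(37L, 2L, 5L))
  # consecutive recorded positions can differ by at most 8 steps of motion
  diffs <- apply(rep1$trajectories, 3, function(m)
    rowSums(abs(m[-1, ] - m[-37, ])))
  expect_true(all(diffs <= 8))
  # trajectory endpoints are occupied sites of the final state
  for (t in 1:5) {
    endpoint <- rep1$trajectories[37, , t]
    expect_true(rep1$final_state$occupancy[endpoint[2] + 1, endpoint[1] + 1])
  }

  # no proliferation conserves the population exactly
  rep0 <- run_replicate(scratch_design(), model_params(0.25, 0))
  expect_equal(cell_count(rep0$final_state), 24)
})

test_that("mean growth is bounded by the crowding-free branching law", {
  set.seed(505)
  d <- scratch_design()
  finals <- replicate(1000, cell_count(run_replicate(d, true_params())$final_state))
  upper <- 24 * 1.0025^288  # aborted births can only reduce growth
  expect_gt(mean(finals), 24)
  expect_lte(mean(finals), upper)
})

test_that("datasets are reproducible from the master seed", {
  d <- scratch_design(n_replicates = 3)
  a <- generate_observed_dataset(d, true_params(), seed = 99)
  b <- generate_observed_dataset(d, true_params(), seed = 99)
  expect_identical(a$replicates, b$replicates)
  for (s in 1:5) {
    c2 <- generate_observed_dataset(d, true_params(), seed = 1000 + s)
    expect_false(identical(a$replicates[[1]]$final_state$cells,
                           c2$replicates[[1]]$final_state$cells))
  }
})

test_that("single-cell mean squared displacement follows p_move * n", {
  set.seed(606)
  cfg <- lattice_config(n_rows = 61, n_cols = 61)
  p <- model_params(0.5, 0)
  n_steps <- 12
  n_trials <- 10000
  msd <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    st <- lattice_state(rbind(c(30, 30)), cfg)
    for (s in seq_len(n_steps)) st <- simulation_step(st, p)
    msd[i] <- (st$cells[1, 1] - 30)^2 + (st$cells[1, 2] - 30)^2
  }
  se <- stats::sd(msd) / sqrt(n_trials)
  expect_lt(abs(mean(msd) - p$p_move * n_steps), 3 * se)
})

test_that("continuum rates evaluate the lattice-to-continuum formulas", {
  rates <- continuum_rates(true_params(), lattice_config())
  expect_equal(unname(rates["diffusivity"]), 527.34375)
  expect_equal(unname(rates["prolif_rate"]), 0.06)
  expect_equal(unname(continuum_rates(model_params(0, 0.0025))["diffusivity"]),
               0)
})

test_that("an observation window restricts cells to the sub-lattice", {
  set.seed(707)
  big <- lattice_config(n_rows = 48, n_cols = 64)
  rep1 <- run_replicate(design_spec(seeded_rows = 12, n_initial = 48),
                        true_params(), big)
  win <- observation_window(rep1$final_state, 24, 32)
  expect_true(all(win$cells[, 1] < 32) && all(win$cells[, 2] < 24))
  expect_equal(dim(win$occupancy), c(24L, 32L))
  expect_lte(cell_count(win), cell_count(rep1$final_state))
})
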