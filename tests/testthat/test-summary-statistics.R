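test_that("cell count equals a brute-force grid sum", {
  cfg <- lattice_config()
  empty <- lattice_state(matrix(integer(0), 0, 2), cfg)
  expect_equal(cell_count(empty), 0)
  set.seed(11)
  for (i in 1:20) {
    st <- random_state(cfg)
    expect_equal(cell_count(st), sum(st$occupancy))
  }
})

test_that("largest cluster matches an independent flood-fill oracle", {
  cfg <- lattice_config()
  one <- lattice_state(rbind(c(3, 3)), cfg)
  expect_equal(largest_cluster(one, 4), 1)
  expect_equal(largest_cluster(one, 8), 1)
  diagonal <- lattice_state(rbind(c(0, 0), c(1, 1)), cfg)
  expect_equal(largest_cluster(diagonal, 4), 1)
  expect_equal(largest_cluster(diagonal, 8), 2)
  empty <- lattice_state(matrix(integer(0), 0, 2), cfg)
  expect_equal(largest_cluster(empty, 4), 0)

  set.seed(22)
  small <- lattice_config(n_rows = 8, n_cols = 10)
  for (i in 1:200) {
    st <- random_state(small, n_cells = sample.int(40, 1))
    k4 <- largest_cluster(st, 4)
    k8 <- largest_cluster(st, 8)
    expect_equal(k4, oracle_largest_cluster(st$occupancy, 4L))
    expect_equal(k8, oracle_largest_cluster(st$occupancy, 8L))
    expect_true(k4 <= k8 && k8 <= cell_count(st))
  }
})

test_that("binning variance evaluates the quadrat deviation formula", {
  cfg <- lattice_config()
  # all 24 cells packed into a single 8x8 quadrat of the 12 quadrats
  packed <- lattice_state(cbind(rep(0:5, 4), rep(0:3, each = 6)), cfg)
  expect_equal(binning_variance(packed, 8), (24 - 2)^2 + 11 * 4)  # 528
  # one cell per quadrat: zero deviation
  centres <- as.matrix(expand.grid(x = c(3, 11, 19, 27), y = c(3, 11, 19)))
  expect_equal(binning_variance(lattice_state(centres, cfg), 8), 0)
  expect_error(binning_variance(packed, 5), "divide")
})

test_that("Manhattan displacement averages summed L1 increments", {
  # one moving cell (0,0)->(1,0)->(1,1), four stationary
  traj <- array(0L, c(3, 2, 5))
  traj[, , 1] <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(manhattan_displacement(traj), 0.4)
  expect_equal(manhattan_displacement(array(2L, c(5, 2, 3))), 0)
  # the default protocol yields 36 increments per tracked cell
  set.seed(33)
  rep1 <- run_replicate(scratch_design(), true_params())
  expect_equal(dim(rep1$trajectories)[1] - 1, 36)
})

test_that("tortuosity is path length over net displacement, excluding degenerate cells", {
  mono <- array(0L, c(3, 2, 1))
  mono[, , 1] <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(tortuosity(mono), 1)
  loop <- array(0L, c(3, 2, 2))
  loop[, , 1] <- rbind(c(0, 0), c(1, 0), c(0, 0))  # degenerate: net 0
  loop[, , 2] <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(tortuosity(loop), 1)  # only the second cell contributes
  loop2 <- loop[, , 1, drop = FALSE]
  expect_true(is.na(tortuosity(loop2)))

  # tortuosity >= 1 whenever defined (L1 triangle inequality)
  set.seed(44)
  for (i in 1:50) {
    tr <- array(cumsum(sample(c(-1L, 0L, 1L), 10 * 2 * 3, replace = TRUE)),
                c(10, 2, 3))
    g <- tortuosity(tr)
    if (!is.na(g)) expect_gte(g, 1)
  }
})

test_that("gyration tensor smallest eigenvalue matches hand algebra", {
  cfg <- lattice_config()
  expect_equal(gyration_min_eigenvalue(
    lattice_state(rbind(c(4, 7), c(9, 2)), cfg)), 0)  # rank-1 pair tensor
  tri <- lattice_state(rbind(c(0, 0), c(1, 0), c(0, 1)), cfg)
  expect_equal(gyration_min_eigenvalue(tri), 1 / 9)
  expect_equal(gyration_min_eigenvalue(tri, absolute = TRUE), 1 / 9)
  row3 <- lattice_state(cbind(0:4, rep(2L, 5)), cfg)
  expect_equal(gyration_min_eigenvalue(row3), 0)
  one <- lattice_state(rbind(c(1, 1)), cfg)
  expect_equal(gyration_min_eigenvalue(one), 0)
  # positive semidefinite with signed differences
  set.seed(55)
  for (i in 1:50)
    expect_gte(gyration_min_eigenvalue(random_state(cfg, 30)), -1e-12)
})

test_that("pair correlations count separations as in hand enumeration", {
  cfg <- lattice_config()
  st <- lattice_state(rbind(c(0, 0), c(0, 3), c(5, 3)), cfg)
  cy <- pair_correlation(st, "Y")
  expect_equal(cy[3], 2)
  expect_equal(sum(cy), 2)
  cxy <- pair_correlation(st, "XY")
  expect_equal(cxy[c(3, 5, 8)], c(1, 1, 1))
  expect_equal(sum(cxy), 3)
  # same-row pairs are uncounted by the vertical correlation
  set.seed(66)
  for (i in 1:20) {
    r <- random_state(cfg, 40)
    expect_lte(sum(pair_correlation(r, "Y")), 40 * 39 / 2)
  }
})

test_that("expected pair counts match exhaustive site-pair enumeration", {
  # full 2x1 lattice: q_Y(1) = 1
  expect_equal(expected_pair_count(1, "Y", 2, lattice_config(2, 1)), 1)
  # 2x2 lattice, N = 2, l = 1: site-pair factor 4, rho*rhobar = 1/6
  expect_equal(expected_pair_count(1, "XY", 2, lattice_config(2, 2)), 2 / 3)
  # the closed form's site-pair factor equals the exhaustive count on all
  # lattices up to 6x6 and all realizable separations
  for (R in 2:6) {
    for (C in 2:6) {
      cfg <- lattice_config(R, C)
      rr <- 5 / (C * R) * (4 / (C * R - 1))
      for (l in 1:(R + C - 2)) {
        expect_equal(expected_pair_count(l, "XY", 5, cfg),
                     oracle_site_pairs(R, C, l, "XY") * rr)
        expect_equal(expected_pair_count(l, "Y", 5, cfg),
                     oracle_site_pairs(R, C, l, "Y") * rr)
      }
    }
  }
})

test_that("normalized correlations calibrate to 1 under random placement", {
  expect_equal(normalize_correlation(c(2, 4), c(2, 4)), c(1, 1))
  expect_true(is.na(normalize_correlation(0, 0)))
  # full 2x1 lattice: C_Y(1)/q_Y(1) = 1
  st <- lattice_state(rbind(c(0, 0), c(0, 1)), lattice_config(2, 1))
  q <- expected_pair_count(1, "Y", 2, lattice_config(2, 1))
  expect_equal(normalize_correlation(pair_correlation(st, "Y")[1], q), 1)

  # complete spatial randomness: mean normalized correlation is 1 per l
  set.seed(77)
  cfg <- lattice_config()
  n <- 30L
  qy <- expected_pair_count(1:24, "Y", n, cfg)
  qxy <- expected_pair_count(1:24, "XY", n, cfg)
  accy <- accxy <- matrix(NA_real_, 2000, 24)
  for (i in 1:2000) {
    st <- random_state(cfg, n)
    accy[i, ] <- normalize_correlation(pair_correlation(st, "Y"), qy)
    accxy[i, ] <- normalize_correlation(pair_correlation(st, "XY"), qxy)
  }
  for (mat in list(accy[, qy > 0], accxy)) {
    m <- colMeans(mat)
    se <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
    expect_true(all(abs(m - 1) <= 3 * se))
  }
})

test_that("the full statistic set is consistent with the standalone operations", {
  set.seed(88)
  rep1 <- run_replicate(scratch_design(), true_params())
  s <- compute_statistic_set(rep1)
  expect_length(s, 13L)
  expect_setequal(names(s), summary_statistic_ids())
  lens <- vapply(s, length, 1L)
  expect_true(all(lens[c("Cxy", "Cxy_hat", "Cy", "Cy_hat")] == 24))
  expect_true(all(lens[setdiff(names(s), c("Cxy", "Cxy_hat", "Cy", "Cy_hat"))] == 1))

  st <- rep1$final_state
  expect_equal(s$N, cell_count(st))
  expect_equal(s$kappa4, largest_cluster(st, 4))
  expect_equal(s$kappa8, largest_cluster(st, 8))
  expect_equal(s$Q8, binning_variance(st, 8))
  expect_equal(s$disp, manhattan_displacement(rep1$trajectories))
  expect_equal(s$tort, tortuosity(rep1$trajectories))
  expect_equal(s$gyr, gyration_min_eigenvalue(st))
  expect_equal(s$Cy, as.numeric(pair_correlation(st, "Y")))
  expect_equal(s$Cxy_hat,
               normalize_correlation(pair_correlation(st, "XY"),
                                     expected_pair_count(1:24, "XY",
                                                         cell_count(st),
                                                         st$config)))

  # trajectory statistics depend only on the tracked trajectories
  s2 <- compute_statistic_set(list(final_state = random_state(st$config, 10),
                                   trajectories = rep1$trajectories),
                              c("disp", "tort"))
  expect_equal(s2$disp, s$disp)
  expect_equal(s2$tort, s$tort)
})

test_that("dataset statistics table is tidy and complete", {
  fx <- make_fixtures(3)
  tab <- compute_dataset_statistics(fx$dataset)
  expect_setequal(unique(tab$statistic_id), summary_statistic_ids())
  expect_equal(nrow(tab), 3 * (9 + 4 * 24))
  expect_true(all(tab$l == 1 | tab$statistic_id %in%
                    c("Cxy", "Cxy_hat", "Cy", "Cy_hat")))
})
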