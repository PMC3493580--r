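test_that("constant trajectory gives the zero covariance model", {
  cm <- build_covariance(make_peptide_traj(4, 5))
  expect_equal(max(abs(cm$matrix)), 0)
  expect_equal(cm$trace, 0)
  expect_true(all(cm$eigenvalues == 0))
})

test_that("two frames displaced along an internal mode give |d|^2/4", {
  set.seed(40)
  n <- 8
  d_unit <- random_internal_modes(n, 1, seed = 40)[, 1]
  amp <- 0.6
  base <- gen_gaussian_traj(n, NULL, 0, 2, seed = 40)
  coords <- base$coords
  coords[2, , ] <- coords[2, , ] +
    matrix(amp * d_unit, ncol = 3, byrow = TRUE)
  tr2 <- trajectory(base$atoms, coords)
  cm <- build_covariance(tr2, fit = FALSE) # frames differ by a pure mode
  expect_equal(cm$eigenvalues[1], amp^2 / 4, tolerance = 1e-10)
  expect_lt(cm$eigenvalues[2], 1e-10)
  overlap <- abs(sum(cm$eigenvectors[, 1] * d_unit))
  expect_equal(overlap, 1, tolerance = 1e-8)
  # with internal superposition the answer is the same up to the (small)
  # nonlinear coupling of a finite displacement to the rigid-body fit
  cm_fit <- build_covariance(tr2)
  expect_equal(cm_fit$eigenvalues[1], amp^2 / 4, tolerance = 1e-3)
})

test_that("covariance model satisfies its structural invariants", {
  V <- random_internal_modes(10, 2, seed = 50)
  tr <- gen_gaussian_traj(10, list(list(direction = V[, 1], variance = 0.2),
                                   list(direction = V[, 2], variance = 0.1)),
                          1e-4, 2000, seed = 50)
  cm <- build_covariance(tr)
  expect_lt(max(abs(cm$matrix - t(cm$matrix))), 1e-10)
  expect_true(all(cm$eigenvalues >= -1e-10))
  expect_equal(sum(cm$eigenvalues), cm$trace, tolerance = 1e-8)
  G <- crossprod(cm$eigenvectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  # trace identity with RMSF on the same selection
  rf <- per_atom_rmsf(tr)
  expect_equal(sum(rf$value_nm^2), cm$trace, tolerance = 1e-10)
})

test_that("eigenvalue spectrum is invariant under global rotation", {
  V <- random_internal_modes(6, 1, seed = 60)
  tr <- gen_gaussian_traj(6, list(list(direction = V[, 1], variance = 0.3)),
                          1e-3, 500, seed = 60)
  cm1 <- build_covariance(tr)
  set.seed(61)
  cm2 <- build_covariance(rigid_move(tr))
  expect_equal(cm1$eigenvalues, cm2$eigenvalues, tolerance = 1e-8)
})

test_that("projection reproduces the spectrum and centres the mean", {
  V <- random_internal_modes(10, 2, seed = 70)
  tr <- gen_gaussian_traj(10, list(list(direction = V[, 1], variance = 0.4),
                                   list(direction = V[, 2], variance = 0.2)),
                          1e-4, 3000, seed = 70)
  cm <- build_covariance(tr)
  pr <- project_trajectory(tr, cm)
  v1 <- mean((pr$p1 - mean(pr$p1))^2)
  v2 <- mean((pr$p2 - mean(pr$p2))^2)
  expect_equal(v1, cm$eigenvalues[1], tolerance = 1e-6)
  expect_equal(v2, cm$eigenvalues[2], tolerance = 1e-6)

  mean_traj <- trajectory(tr$atoms, array(cm$mean_structure,
                                          c(1, n_atoms(tr), 3)))
  pm <- project_trajectory(mean_traj, cm)
  expect_lt(max(abs(c(pm$p1, pm$p2))), 1e-8)

  expect_error(project_trajectory(tr, cm, k = c(1, 999)), "out of range")
})

test_that("basin extraction recovers a single Gaussian cloud's centre", {
  set.seed(80)
  n <- 20000
  pr <- as_projection(rnorm(n, sd = 0.3), rnorm(n, sd = 0.3))
  b <- extract_basins(pr, grid_bins = 30, n_basins = 1)
  # histogram-mode quantisation dominates the Monte Carlo error of the mean
  cell <- diff(range(pr$p1)) * 1.1 / 30
  expect_lt(abs(b$center_p1), 2 * cell)
  expect_lt(abs(b$center_p2), 2 * cell)
  expect_equal(b$population, 1)
  expect_true(b$representative_frame %in% seq_len(n))
})

test_that("two-state basins match the generator's labels", {
  ts <- gen_two_state_loop(8, displacement = 1.0, open_fraction = 0.45,
                           n_frames = 6000, jitter = 1e-4, seed = 90)
  cm <- build_covariance(ts$trajectory)
  pr <- project_trajectory(ts$trajectory, cm)
  b <- extract_basins(pr, 50, 2)
  expect_equal(nrow(b), 2L)
  asg <- attr(b, "assignment")
  agree <- max(mean((asg == 1) == (ts$labels == "open")),
               mean((asg == 2) == (ts$labels == "open")))
  expect_gte(agree, 0.99)
  expect_equal(sum(b$population), 1)
  # representatives live in their own basins
  expect_equal(asg[b$representative_frame], b$basin)
})

test_that("asking for more basins than exist is answered honestly", {
  set.seed(81)
  pr <- as_projection(rnorm(8000, sd = 0.2), rnorm(8000, sd = 0.2))
  expect_warning(b <- extract_basins(pr, 30, n_basins = 3), "only")
  expect_lt(nrow(b), 3L)
  expect_true(attr(b, "underpopulated"))
})

test_that("conformational-space overlap has its closed-form anchors", {
  set.seed(82)
  a <- as_projection(rnorm(4000), rnorm(4000))
  expect_equal(compare_conformational_spaces(list(x = a, y = a))["x", "y"], 1)

  b <- as_projection(rnorm(4000) + 100, rnorm(4000))
  M <- compare_conformational_spaces(list(a = a, b = b))
  expect_equal(M["a", "b"], 0)
  expect_equal(diag(M), c(a = 1, b = 1))

  # uniform lattices sharing exactly half their support
  g <- expand.grid(x = seq(0.005, 0.995, by = 0.01),
                   y = seq(0.005, 0.995, by = 0.01))
  left <- as_projection(g$x, g$y)                  # support [0,1]
  right <- as_projection(g$x + 0.5, g$y)           # support [0.5,1.5]
  M2 <- compare_conformational_spaces(list(l = left, r = right),
                                      grid_bins = 40)
  expect_equal(M2["l", "r"], 0.5, tolerance = 0.06)
  expect_error(compare_conformational_spaces(list(as_projection(numeric(0),
                                                                numeric(0)))),
               "empty")
})

test_that("planted eigenvector directions are recovered to a few degrees", {
  V <- random_internal_modes(20, 2, seed = 95)
  tr <- gen_gaussian_traj(20, list(list(direction = V[, 1], variance = 0.5),
                                   list(direction = V[, 2], variance = 0.3)),
                          1e-3, 8000, seed = 95)
  cm <- build_covariance(tr)
  ang <- function(u, v) acos(pmin(1, abs(sum(u * v)))) * 180 / pi
  expect_lt(ang(cm$eigenvectors[, 1], V[, 1]), 5)
  expect_lt(ang(cm$eigenvectors[, 2], V[, 2]), 5)
})
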