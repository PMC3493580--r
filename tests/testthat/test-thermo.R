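test_that("lambda tables tolerate comments and mixed separators", {
  f <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@ xaxis label", "0.0 3.5", "0.5,2.1",
               "  1.0\t0.7"), f)
  tab <- read_dhdl_table(f)
  expect_equal(tab$x, c(0, 0.5, 1))
  expect_equal(tab$dhdl, c(3.5, 2.1, 0.7))

  bad <- withr::local_tempfile()
  writeLines(c("0.0 1.0", "oops"), bad)
  expect_error(read_dhdl_table(bad), "unparsable line 2")
})

test_that("profile validation enforces the grid and sample contracts", {
  expect_error(ti_profile(numeric(0), list()), "empty")
  expect_error(ti_profile(c(0, 0.5), list(1:2, 1:2)), "span")
  expect_error(ti_profile(c(0, 0.5, 0.4, 1), rep(list(1:2), 4)), "increasing")
  expect_error(ti_profile(c(0, 1), list(1:2, 3)), "at least 2 samples")
  prof <- ti_profile(c(0, 1), list(c(1, 2), c(3, 4)), temperature = 310)
  expect_equal(attr(prof, "temperature"), 310)
  expect_equal(attr(prof, "softcore")$alpha, 1.51)
})

test_that("TI quadrature: null path, linearity, and the harmonic oracle", {
  zero <- ti_profile(c(0, 0.5, 1), rep(list(rep(0, 9)), 3))
  fe0 <- integrate_ti(zero)
  expect_equal(fe0$value, 0)
  expect_equal(fe0$standard_error, 0)

  prof <- gen_ti_samples(1, 4, 300, n_per_lambda = 500, seed = 31)
  fe <- integrate_ti(prof)
  scaled <- prof
  scaled$dhdl <- 2.5 * scaled$dhdl
  expect_equal(integrate_ti(scaled)$value, 2.5 * fe$value, tolerance = 1e-12)

  # five (k1, k2, T) cases, each within 3 propagated SE of the closed form
  cases <- data.frame(k1 = c(1, 2, 0.5, 3, 1), k2 = c(4, 2.5, 5, 1, 10),
                      t = c(300, 323, 280, 310, 350))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      p <- gen_ti_samples(k1, k2, t, n_per_lambda = 2000, seed = 100 + i)
      f <- integrate_ti(p)
      truth <- 8.314462618e-3 * t / 2 * log(k2 / k1)
      expect_lt(abs(f$value - truth), 3 * f$standard_error + 0.02)
    })
  }
})

test_that("noise-free quadrature converges at the trapezoid rate", {
  lam <- seq(0, 1, length.out = 101)
  exact <- lapply(lam, function(l) rep(0.5 * 3 * RT300 / ((1 - l) + 4 * l), 3))
  fe <- integrate_ti(ti_profile(lam, exact))
  expect_lt(abs(fe$value - RT300 / 2 * log(4)), 1e-3)
  # Simpson's rule does even better on the same grid
  fes <- integrate_ti(ti_profile(lam, exact), method = "simpson")
  expect_lt(abs(fes$value - RT300 / 2 * log(4)), 1e-6)
  expect_error(integrate_ti(ti_profile(c(0, 0.3, 1), exact[c(1, 31, 101)]),
                            method = "simpson"), "uniform")
})

test_that("relative free energies propagate errors against the reference", {
  res <- tibble::tibble(system = c("a", "b"), value = c(10, 4),
                        se = c(3, 4), temperature = 300)
  out <- relative_binding_ddg(res, "b")
  expect_equal(out$ddmu[out$system == "a"], 6)
  expect_equal(out$se[out$system == "a"], 5) # sqrt(9 + 16)
  expect_equal(out$ddmu[out$system == "b"], 0)
  expect_equal(out$se[out$system == "b"], 0)

  # permutation invariance
  out2 <- relative_binding_ddg(res[2:1, ], "b")
  expect_equal(dplyr::arrange(out2, system), dplyr::arrange(out, system))

  solo <- relative_binding_ddg(tibble::tibble(system = "x", value = 7,
                                              se = 2, temperature = 300), "x")
  expect_equal(solo$ddmu, 0)
  expect_equal(solo$se, 0)

  mixed <- res
  mixed$temperature <- c(300, 323)
  expect_error(relative_binding_ddg(mixed, "b"), "one temperature")
  expect_error(relative_binding_ddg(res, "zz"), "not among")
})

test_that("entropy decomposition: identities and the two-temperature table", {
  same <- list(value = 5, standard_error = 1, temperature = 300)
  same2 <- list(value = 5, standard_error = 1, temperature = 323)
  ed <- entropy_decomposition(same, same2)
  expect_equal(ed$dds, 0)
  expect_true(ed$consistent_with_zero_entropy)

  # ddG(T) = a - s*T exactly recovers s with zero error
  a <- 40; s <- 0.12
  lin <- entropy_decomposition(
    list(value = a - s * 300, standard_error = 0, temperature = 300),
    list(value = a - s * 323, standard_error = 0, temperature = 323))
  expect_equal(lin$dds, s, tolerance = 1e-12)
  expect_equal(lin$ddh, a, tolerance = 1e-10)

  # the bundled two-temperature binding table: 16+/-12 vs 11+/-16
  ed1a <- entropy_decomposition(
    list(value = 16, standard_error = 12, temperature = 300),
    list(value = 11, standard_error = 16, temperature = 323))
  expect_equal(ed1a$dds, 5 / 23, tolerance = 1e-10)
  expect_equal(ed1a$dds_se, 20 / 23, tolerance = 1e-10)
  expect_true(ed1a$consistent_with_zero_entropy)

  expect_error(entropy_decomposition(same, same), "T2 > T1")
})

test_that("Cheng-Prusoff conversion reduces correctly for shared assays", {
  mk <- function(ic50, s = 1e-5, km = 2e-5) inhibition_data(ic50, s, km)
  expect_equal(ic50_to_ddmu(mk(3e-6), mk(3e-6)), 0)
  expect_equal(ic50_to_ddmu(mk(1e-6), mk(exp(1) * 1e-6), 300), RT300,
               tolerance = 1e-10)
  expect_equal(ic50_to_ddmu(mk(1e-7), mk(1e-5), 300), RT300 * log(100),
               tolerance = 1e-10)
  expect_equal(RT300 * log(100), 11.48, tolerance = 1e-3)
  # unequal assay conditions: warn and use the full form
  expect_warning(
    full <- ic50_to_ddmu(mk(1e-6, s = 1e-5), mk(1e-6, s = 3e-5), 300),
    "differ")
  expect_equal(full, RT300 * log((1 + 0.5) / (1 + 1.5)), tolerance = 1e-10)
})

test_that("tautomer equilibrium matches a direct Boltzmann summation", {
  one_each <- data.frame(tautomer = c("a", "b"), gas_rel = c(-10, -5),
                         hydration = c(-20, -25))
  eq <- tautomer_equilibrium(one_each, 300)
  expect_equal(eq$K, 1)
  expect_equal(eq$delta_mu, 0, tolerance = 1e-12)

  two_state <- data.frame(tautomer = c("a", "b"), gas_rel = c(0, 0),
                          hydration = c(-72.0, -79.1))
  eq2 <- tautomer_equilibrium(two_state, 300)
  expect_equal(eq2$K, exp(-7.1 / RT300), tolerance = 1e-12)
  expect_equal(eq2$K, 0.058, tolerance = 0.01)

  # brute-force oracle on a random 10-conformer table
  set.seed(37)
  tab <- data.frame(tautomer = rep(c("a", "b"), each = 5),
                    gas_rel = rnorm(10, 0, 4), hydration = rnorm(10, -70, 5))
  eq3 <- tautomer_equilibrium(tab, 300)
  g <- tab$gas_rel + tab$hydration
  K_direct <- sum(exp(-g[tab$tautomer == "a"] / RT300)) /
    sum(exp(-g[tab$tautomer == "b"] / RT300))
  expect_equal(eq3$K, K_direct, tolerance = 1e-12)
  expect_equal(eq3$delta_mu, -RT300 * log(eq3$K), tolerance = 1e-10)

  # duplicating a conformer doubles that side's partition term
  dup <- rbind(tab, tab[1, ])
  eq4 <- tautomer_equilibrium(dup, 300)
  w1 <- exp(-g[1] / RT300) / sum(exp(-g[tab$tautomer == "a"] / RT300))
  expect_equal(eq4$K / eq3$K, 1 + w1, tolerance = 1e-10)

  # an unreachable conformer (G -> +inf) changes nothing
  far <- rbind(tab, data.frame(tautomer = "a", gas_rel = 1e7, hydration = 0))
  expect_equal(tautomer_equilibrium(far, 300)$K, eq3$K, tolerance = 1e-12)

  expect_error(tautomer_equilibrium(tab[tab$tautomer == "a", ], 300),
               "each tautomer")
})

test_that("the linkage cycle combines binding and tautomer equilibria", {
  expect_equal(bound_tautomer_ratio(1, 5, 5, 300), 1)
  # cancellation construction: K = 0.5 against ddmu gap of -RT ln 2
  expect_equal(bound_tautomer_ratio(0.5, -RT300 * log(2), 0, 300), 1,
               tolerance = 1e-12)
  # the bundled worked example
  r <- bound_tautomer_ratio(0.21, 16, 0, 300)
  expect_equal(r, 3.5e-4, tolerance = 0.05)
  # monotone in K and antitone in the free-energy gap
  ks <- c(0.1, 0.2, 0.5, 1, 2)
  expect_true(all(diff(vapply(ks, bound_tautomer_ratio, numeric(1),
                              ddmu_a = 3, ddmu_b = 1)) > 0))
  gaps <- c(-5, -1, 0, 2, 6)
  expect_true(all(diff(vapply(gaps, function(g) {
    bound_tautomer_ratio(0.3, g, 0)
  }, numeric(1))) < 0))
  # an equilibrium object carries its own temperature
  eq <- tautomer_equilibrium(mmp2_conformer_table(), 300)
  expect_equal(bound_tautomer_ratio(eq, 0, 0), eq$K)
})

test_that("bundled tables load with the expected shape", {
  b <- mmp2_binding_table()
  expect_equal(nrow(b), 6L)
  expect_setequal(unique(b$temperature), c(300, 323))
  cf <- mmp2_conformer_table()
  expect_equal(nrow(cf), 6L)
  expect_setequal(unique(cf$tautomer), c("a", "b"))
})
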