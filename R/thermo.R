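#' Thermodynamic-integration profile
#'
#' Holds per-lambda samples of the coupling derivative dH/dlambda along an
#' alchemical path, the simulation temperature, and (descriptive only) the
#' engine-side soft-core metadata. The profile is stored long: one row per
#' sample.
#'
#' @param lambdas Strictly increasing coupling-parameter grid spanning
#'   `[0, 1]`.
#' @param samples List (one element per lambda) of numeric dH/dlambda
#'   samples in kJ/mol, each of length >= 2.
#' @param temperature Temperature in K.
#' @param softcore Metadata list carried through to results (defaults
#'   `alpha = 1.51`, `sigma = 0.3` nm, `delta_lambda = 0.001`); never used
#'   numerically.
#' @return A `ti_profile` tibble with columns `lambda` and `dhdl`;
#'   attributes `temperature` and `softcore`.
#' @export
ti_profile <- function(lambdas, samples, temperature = 300,
                       softcore = list(alpha = 1.51, sigma = 0.3,
                                       delta_lambda = 0.001)) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) == 0L) abort("empty lambda grid")
  if (length(lambdas) < 2L || any(diff(lambdas) <= 0) ||
      lambdas[1] != 0 || lambdas[length(lambdas)] != 1) {
    abort("`lambdas` must be strictly increasing and span [0, 1]")
  }
  if (length(samples) != length(lambdas)) {
    abort("`samples` must have one element per lambda")
  }
  if (any(vapply(samples, length, integer(1)) < 2L)) {
    abort("every lambda needs at least 2 samples")
  }
  out <- tibble(
    lambda = rep(lambdas, vapply(samples, length, integer(1))),
    dhdl = unlist(samples))
  attr(out, "temperature") <- temperature
  attr(out, "softcore") <- softcore
  class(out) <- c("ti_profile", class(out))
  out
}

#' Read a two-column lambda table (XVG-compatible)
#'
#' Whitespace- or comma-separated two-column text: first column lambda (or
#' time), second dH/dlambda in kJ/mol. Lines starting with `#` or `@` are
#' ignored.
#'
#' @param path File path.
#' @return Tibble with columns `x` and `dhdl`.
#' @export
read_dhdl_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*[#@]", ln) & nzchar(trimws(ln))]
  if (!length(ln)) abort(sprintf("no data rows in %s", path))
  parts <- strsplit(trimws(ln), "[,[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) abort(sprintf("unparsable line %d in %s", bad[1], path))
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(x) || anyNA(y)) abort(sprintf("non-numeric data in %s", path))
  tibble(x = x, dhdl = y)
}

.new_free_energy <- function(value, se, temperature) {
  structure(list(value = value, standard_error = se,
                 temperature = temperature),
            class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("Delta F = %.4g +/- %.3g kJ/mol at %g K\n",
              x$value, x$standard_error, x$temperature))
  invisible(x)
}

#' Thermodynamic-integration quadrature
#'
#' The free-energy difference is the lambda integral of the per-lambda mean
#' coupling derivative, evaluated by the trapezoidal rule on the profile's
#' grid (robust on non-uniform grids; Simpson's rule available for uniform
#' grids). The standard error of each per-lambda mean is estimated from
#' `n_blocks` contiguous blocks and propagated through the quadrature
#' weights: `SE^2 = sum_k w_k^2 SE_k^2`.
#'
#' @param profile A [ti_profile()].
#' @param method `"trapezoid"` (default) or `"simpson"` (requires an odd
#'   number of uniformly spaced points).
#' @param n_blocks Blocks per lambda for the standard error (default 3).
#' @return A `free_energy` object (kJ/mol).
#' @export
integrate_ti <- function(profile, method = c("trapezoid", "simpson"),
                         n_blocks = 3L) {
  stopifnot(inherits(profile, "ti_profile"))
  method <- match.arg(method)
  lam <- sort(unique(profile$lambda))
  if (length(lam) < 2L) abort("need at least 2 lambda points")
  means <- ses <- numeric(length(lam))
  for (i in seq_along(lam)) {
    s <- profile$dhdl[profile$lambda == lam[i]]
    be <- block_standard_error(s, n_blocks)
    means[i] <- mean(s)
    ses[i] <- be$standard_error
  }
  w <- .quadrature_weights(lam, method)
  .new_free_energy(sum(w * means), sqrt(sum(w^2 * ses^2)),
                   attr(profile, "temperature") %||% NA_real_)
}

.quadrature_weights <- function(lam, method) {
  n <- length(lam)
  if (method == "trapezoid") {
    h <- diff(lam)
    w <- numeric(n)
    w[1] <- h[1] / 2
    w[n] <- h[n - 1] / 2
    if (n > 2) w[2:(n - 1)] <- (h[-(n - 1)] + h[-1]) / 2
    return(w)
  }
  if (n < 3L || n %% 2L == 0L) abort("Simpson's rule needs an odd number of points")
  h <- diff(lam)
  if (max(abs(h - h[1])) > 1e-10) abort("Simpson's rule needs a uniform grid")
  w <- rep(c(2, 4), length.out = n)
  w[1] <- w[n] <- 1
  w * h[1] / 3
}

#' Relative binding free energies against a reference system
#'
#' Subtracts the reference system's free energy from every system's and
#' propagates the quadrature standard errors in quadrature,
#' `SE = sqrt(SE_i^2 + SE_ref^2)`. The reference row is reported as exactly
#' 0 with SE 0, the usual convention for a relative scale.
#'
#' @param results Data frame with columns `system`, `value`, `se` and
#'   `temperature` (one temperature only), or a named list of
#'   `free_energy` objects.
#' @param reference System label used as the zero of the scale.
#' @return Tibble with columns `system`, `ddmu` (kJ/mol), `se` and
#'   `temperature`.
#' @export
relative_binding_ddg <- function(results, reference) {
  if (!is.data.frame(results)) {
    stopifnot(all(vapply(results, inherits, logical(1), "free_energy")))
    results <- tibble(
      system = names(results),
      value = vapply(results, `[[`, numeric(1), "value"),
      se = vapply(results, `[[`, numeric(1), "standard_error"),
      temperature = vapply(results, `[[`, numeric(1), "temperature"))
  }
  results <- as_tibble(results)
  if (!reference %in% results$system) {
    abort(sprintf("reference system '%s' not among results", reference))
  }
  if (length(unique(results$temperature)) != 1L) {
    abort("all results must share one temperature")
  }
  ref <- results[results$system == reference, ]
  out <- results
  out$ddmu <- out$value - ref$value
  out$se <- ifelse(out$system == reference, 0,
                   sqrt(out$se^2 + ref$se^2))
  out[, c("system", "ddmu", "se", "temperature")]
}

#' Enthalpy/entropy decomposition from two-temperature free energies
#'
#' Using the finite-difference relation `ddS = -(ddG(T2) - ddG(T1)) /
#' (T2 - T1)` and `ddH = ddG(T1) + T1 * ddS`, with standard errors
#' propagated in quadrature. The `consistent_with_zero_entropy` flag is
#' `TRUE` when `|ddS|` does not exceed its own standard error, i.e. when
#' the data give no evidence of a temperature dependence and the free-energy
#' difference is to be read as enthalpic.
#'
#' @param ddg_t1,ddg_t2 `free_energy` objects (or lists with `value`,
#'   `standard_error`, `temperature`) at two different temperatures,
#'   `T2 > T1`.
#' @return A list of class `entropy_decomposition` with `dds`, `dds_se`
#'   (kJ/(mol K)), `ddh`, `ddh_se` (kJ/mol), `t1`, `t2` and
#'   `consistent_with_zero_entropy`.
#' @export
entropy_decomposition <- function(ddg_t1, ddg_t2) {
  v1 <- ddg_t1$value; s1 <- ddg_t1$standard_error; t1 <- ddg_t1$temperature
  v2 <- ddg_t2$value; s2 <- ddg_t2$standard_error; t2 <- ddg_t2$temperature
  if (!is.finite(t1) || !is.finite(t2) || t2 <= t1) {
    abort("need two distinct temperatures with T2 > T1")
  }
  dt <- t2 - t1
  dds <- -(v2 - v1) / dt
  dds_se <- sqrt(s1^2 + s2^2) / dt
  ddh <- v1 + t1 * dds
  ddh_se <- sqrt(s1^2 + t1^2 * dds_se^2)
  structure(list(dds = dds, dds_se = dds_se, ddh = ddh, ddh_se = ddh_se,
                 t1 = t1, t2 = t2,
                 consistent_with_zero_entropy = abs(dds) <= dds_se),
            class = "entropy_decomposition")
}

#' @export
print.entropy_decomposition <- function(x, ...) {
  cat(sprintf("ddS = %.4g +/- %.3g kJ/(mol K); ddH = %.4g +/- %.3g kJ/mol\n",
              x$dds, x$dds_se, x$ddh, x$ddh_se))
  cat(if (x$consistent_with_zero_entropy)
        "entropy indistinguishable from zero at 1 SE\n"
      else "entropy differs from zero at 1 SE\n")
  invisible(x)
}

#' Inhibition data for the Cheng-Prusoff conversion
#' @param ic50 Half-maximal inhibitory concentration, molar.
#' @param substrate_conc Substrate concentration S, molar.
#' @param km Michaelis constant, molar.
#' @return A list of class `inhibition_data`.
#' @export
inhibition_data <- function(ic50, substrate_conc, km) {
  if (any(c(ic50, substrate_conc, km) <= 0)) abort("all quantities must be positive")
  structure(list(ic50 = ic50, substrate_conc = substrate_conc, km = km),
            class = "inhibition_data")
}

#' Relative binding free energy from IC50 values (Cheng-Prusoff)
#'
#' Converts each IC50 to an inhibition constant, `Ki = IC50 / (1 + S/Km)`,
#' and returns `RT ln(Ki_b / Ki_a)` in kJ/mol. When the two compounds were
#' assayed at the same substrate concentration and Michaelis constant the
#' conversion factor cancels and the result reduces to
#' `RT ln(IC50_b / IC50_a)`; with unequal assay conditions the full form is
#' used and a warning notes that the reduction does not apply.
#'
#' @param a,b [inhibition_data()] for the two compounds.
#' @param temperature Temperature in K.
#' @return Relative binding free energy, kJ/mol.
#' @export
ic50_to_ddmu <- function(a, b, temperature = 300) {
  stopifnot(inherits(a, "inhibition_data"), inherits(b, "inhibition_data"))
  rt <- .R_GAS * temperature
  if (a$substrate_conc != b$substrate_conc || a$km != b$km) {
    warn("assay conditions differ; using the full Cheng-Prusoff form")
  }
  ki_a <- a$ic50 / (1 + a$substrate_conc / a$km)
  ki_b <- b$ic50 / (1 + b$substrate_conc / b$km)
  rt * log(ki_b / ki_a)
}

#' Tautomeric equilibrium constant from a conformer free-energy table
#'
#' Each conformer's solution free energy is its gas-phase relative free
#' energy plus its hydration (excess solvation) free energy. Per tautomer,
#' conformers are combined by Boltzmann summation,
#' `mu_X = -RT ln sum_i exp(-G_i / RT)` (computed by overflow-safe
#' log-sum-exp), and the equilibrium constant is
#' `K = [a]/[b] = exp(-(mu_a - mu_b) / RT)`.
#'
#' @param conformers Data frame with columns `tautomer` (values `"a"` /
#'   `"b"`), `gas_rel` and `hydration` (kJ/mol); an optional `species`
#'   column labels conformers.
#' @param temperature Temperature in K.
#' @return A list of class `tautomer_equilibrium` with `K`
#'   (dimensionless, `[a]/[b]`), `delta_mu = -RT ln K` (kJ/mol),
#'   `temperature` and the per-tautomer chemical potentials `mu`.
#' @export
tautomer_equilibrium <- function(conformers, temperature = 300) {
  conformers <- as.data.frame(conformers)
  stopifnot(all(c("tautomer", "gas_rel", "hydration") %in% names(conformers)))
  if (!all(c("a", "b") %in% conformers$tautomer)) {
    abort("need at least one conformer for each tautomer ('a' and 'b')")
  }
  rt <- .R_GAS * temperature
  g <- conformers$gas_rel + conformers$hydration
  lse <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  mu <- vapply(c(a = "a", b = "b"), function(tt) {
    -rt * lse(-g[conformers$tautomer == tt] / rt)
  }, numeric(1))
  delta_mu <- mu[["a"]] - mu[["b"]]
  structure(list(K = exp(-delta_mu / rt), delta_mu = delta_mu,
                 temperature = temperature, mu = mu),
            class = "tautomer_equilibrium")
}

#' @export
print.tautomer_equilibrium <- function(x, ...) {
  cat(sprintf("K ([a]/[b]) = %.4g at %g K (delta mu = %.4g kJ/mol)\n",
              x$K, x$temperature, x$delta_mu))
  invisible(x)
}

#' Bound-tautomer ratio from the binding/tautomerisation linkage cycle
#'
#' For a ligand that exists in solution as two tautomers a and b with
#' equilibrium constant `K_taut = [a]/[b]`, and whose tautomer-specific
#' relative binding free energies are `ddmu_a` and `ddmu_b` (on a common
#' reference scale), the thermodynamic cycle gives the ratio of the two
#' bound complexes as
#' `[complex_a]/[complex_b] = exp(-(ddmu_a - ddmu_b)/RT) * K_taut`.
#'
#' @param k_taut A [tautomer_equilibrium()] or a bare positive number
#'   (`[a]/[b]` in free solution).
#' @param ddmu_a,ddmu_b Relative binding free energies of the two tautomers,
#'   kJ/mol.
#' @param temperature Temperature in K (taken from `k_taut` when it is an
#'   equilibrium object).
#' @return Dimensionless ratio `[complex_a]/[complex_b]`.
#' @export
bound_tautomer_ratio <- function(k_taut, ddmu_a, ddmu_b, temperature = 300) {
  if (inherits(k_taut, "tautomer_equilibrium")) {
    temperature <- k_taut$temperature
    k_taut <- k_taut$K
  }
  if (!is.numeric(k_taut) || k_taut <= 0) abort("`k_taut` must be positive")
  rt <- .R_GAS * temperature
  exp(-(ddmu_a - ddmu_b) / rt) * k_taut
}

#' Bundled relative binding free-energy table
#'
#' Two-temperature relative binding free energies (kJ/mol, with propagated
#' standard errors) for the three studied ligand forms binding the MMP-2
#' catalytic domain, on the scale where the `1b` complex at 300 K is the
#' reference. Shipped as plain CSV in `extdata`.
#'
#' @return Tibble with columns `system`, `temperature`, `ddmu`, `se`.
#' @export
mmp2_binding_table <- function() {
  p <- system.file("extdata", "mmp2_binding_ddmu.csv", package = "tidytraj",
                   mustWork = TRUE)
  as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
}

#' Bundled tautomer conformer free-energy table
#'
#' Gas-phase relative molar free energies at 300 K and hydration (excess
#' solvation) free energies, kJ/mol, for the low-lying conformers of the
#' two pyrazole tautomers of the active ligand, from electronic-structure
#' calculations (consumed as input here). Gas-phase values use a 1.0 M
#' standard state at 300 K.
#'
#' @return Tibble with columns `species`, `tautomer`, `gas_rel`,
#'   `hydration`.
#' @export
mmp2_conformer_table <- function() {
  p <- system.file("extdata", "tautomer_conformers.csv", package = "tidytraj",
                   mustWork = TRUE)
  as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
}
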