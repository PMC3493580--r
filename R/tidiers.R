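#' Tidy a covariance model into its eigenvalue spectrum
#'
#' @param x A `covariance_model`.
#' @param n_values Number of leading eigenvalues to report (default 20, the
#'   informative head of a typical spectrum).
#' @param ... Unused.
#' @return Tibble with columns `index`, `eigenvalue` (nm^2) and
#'   `cumulative_fraction` of the trace.
#' @exportS3Method generics::tidy
tidy.covariance_model <- function(x, n_values = 20L, ...) {
  n <- min(n_values, length(x$eigenvalues))
  tibble(index = seq_len(n),
         eigenvalue = x$eigenvalues[seq_len(n)],
         cumulative_fraction = cumsum(x$eigenvalues[seq_len(n)]) /
           max(x$trace, .Machine$double.eps))
}

#' @exportS3Method generics::glance
glance.covariance_model <- function(x, ...) {
  tibble(n_atoms = length(x$selection), n_frames = x$n_frames,
         trace_nm2 = x$trace,
         lambda1_nm2 = x$eigenvalues[1],
         lambda2_nm2 = x$eigenvalues[2])
}

#' @exportS3Method generics::tidy
tidy.free_energy <- function(x, ...) {
  tibble(estimate = x$value, std.error = x$standard_error,
         temperature = x$temperature)
}

#' @exportS3Method generics::glance
glance.free_energy <- function(x, ...) tidy(x)

#' @exportS3Method generics::tidy
tidy.block_error <- function(x, ...) {
  tibble(estimate = x$mean, std.error = x$standard_error,
         n_blocks = x$n_blocks)
}

#' @exportS3Method generics::tidy
tidy.entropy_decomposition <- function(x, ...) {
  tibble(term = c("ddS", "ddH"),
         estimate = c(x$dds, x$ddh),
         std.error = c(x$dds_se, x$ddh_se),
         unit = c("kJ/(mol K)", "kJ/mol"))
}

#' @exportS3Method generics::glance
glance.entropy_decomposition <- function(x, ...) {
  tibble(dds = x$dds, dds_se = x$dds_se, ddh = x$ddh, ddh_se = x$ddh_se,
         t1 = x$t1, t2 = x$t2,
         consistent_with_zero_entropy = x$consistent_with_zero_entropy)
}

#' @exportS3Method generics::tidy
tidy.tautomer_equilibrium <- function(x, ...) {
  tibble(K = x$K, delta_mu = x$delta_mu, temperature = x$temperature)
}
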