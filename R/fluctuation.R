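.new_fluct_profile <- function(df, kind) {
  stopifnot(kind %in% c("rmsf", "residue_rmsd", "delta_rmsd"))
  out <- as_tibble(df)
  out$kind <- kind
  class(out) <- c("fluct_profile", class(out))
  out
}

#' Per-frame RMSD relative to a reference structure
#'
#' Each frame is superposed on the reference over `fit_selection` and the
#' root-mean-square deviation is then measured over `measure_selection`.
#' Values are invariant to any rigid motion applied to a frame.
#'
#' @param traj A [trajectory()].
#' @param reference Reference coordinates: an `n_atoms x 3` matrix (nm) or a
#'   frame index into `traj` (default 1, the starting structure).
#' @param fit_selection,measure_selection Atom index vectors (see
#'   [select_atoms()]); `NULL` means all atoms. `measure_selection` defaults
#'   to `fit_selection`.
#' @return A tibble with columns `frame`, `time_ps` (if the trajectory has
#'   times) and `rmsd_nm`.
#' @export
rmsd_series <- function(traj, reference = 1L, fit_selection = NULL,
                        measure_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  fit_sel <- .as_selection(fit_selection, traj)
  meas_sel <- if (is.null(measure_selection)) fit_sel
              else .as_selection(measure_selection, traj)
  if (!length(fit_sel) || !length(meas_sel)) abort("selections must be non-empty")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    sp <- superpose(fr, ref, fit_sel)
    vals[f] <- .frame_rmsd(apply_superposition(fr, sp), ref, meas_sel)
  }
  out <- tibble(frame = seq_len(nf), rmsd_nm = vals)
  if (!is.null(traj$times)) out <- tibble(frame = seq_len(nf),
                                          time_ps = traj$times, rmsd_nm = vals)
  out
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed on their iterated mean structure (fit to the mean,
#' recompute the mean, repeat until the mean moves by less than 1e-6 nm or
#' 10 iterations). The RMSF of atom i is the square root of the time-mean
#' squared deviation of its position from its mean position. On a common
#' selection, `sum(RMSF^2)` equals the trace of the positional covariance
#' matrix from [build_covariance()].
#'
#' @inheritParams rmsd_series
#' @return A `fluct_profile` tibble with columns `atom_serial`,
#'   `residue_id`, `value_nm` and `kind = "rmsf"`.
#' @export
per_atom_rmsf <- function(traj, fit_selection = NULL, measure_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) abort("RMSF needs at least 2 frames")
  fit_sel <- .as_selection(fit_selection, traj)
  meas_sel <- if (is.null(measure_selection)) fit_sel
              else .as_selection(measure_selection, traj)
  ft <- .fit_to_iterated_mean(traj$coords, fit_sel)
  vals <- vapply(meas_sel, function(i) {
    d <- ft$coords[, i, , drop = FALSE]
    d <- sweep(matrix(d, nrow = dim(d)[1]), 2, ft$mean[i, ])
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  .new_fluct_profile(
    tibble(atom_serial = traj$atoms$serial[meas_sel],
           residue_id = traj$atoms$residue_id[meas_sel],
           value_nm = vals),
    "rmsf")
}

#' Time-averaged per-residue deviation from a reference structure
#'
#' After superposing each frame globally on the reference over
#' `fit_selection`, the value for residue i is the root of the time-mean
#' squared displacement of its designated atom (default the alpha-carbon)
#' from its reference position. Residues lacking the designated atom are
#' dropped with a warning.
#'
#' @inheritParams rmsd_series
#' @param atom_name Designated atom per residue (default `"CA"`).
#' @return A `fluct_profile` tibble with columns `residue_id`, `value_nm`,
#'   `kind = "residue_rmsd"`.
#' @export
per_residue_rmsd <- function(traj, reference = 1L, fit_selection = NULL,
                             atom_name = "CA") {
  stopifnot(inherits(traj, "trajectory"))
  fit_sel <- .as_selection(fit_selection, traj)
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  idx <- which(traj$atoms$name == atom_name)
  resids <- unique(traj$atoms$residue_id)
  missing <- setdiff(resids, traj$atoms$residue_id[idx])
  if (length(missing)) {
    warn(sprintf("residues without a '%s' atom excluded: %s", atom_name,
                 paste(missing, collapse = ", ")))
  }
  # one designated atom per residue, first occurrence wins
  idx <- idx[!duplicated(traj$atoms$residue_id[idx])]
  fitted <- .fit_frames(traj$coords, ref, fit_sel)
  vals <- vapply(idx, function(i) {
    d <- sweep(matrix(fitted[, i, , drop = FALSE], nrow = dim(fitted)[1]),
               2, ref[i, ])
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  .new_fluct_profile(
    tibble(residue_id = traj$atoms$residue_id[idx], value_nm = vals),
    "residue_rmsd")
}

#' Per-residue deviation difference between a complex and the apo form
#'
#' The elementwise difference `complex - apo` of two per-residue deviation
#' profiles, aligned by residue id. A value of zero at a residue means the
#' ligand leaves that part of the structure unperturbed; positive values
#' localise binding-induced structural change.
#'
#' @param complex_profile,apo_profile `fluct_profile` tibbles from
#'   [per_residue_rmsd()] (or [per_atom_rmsf()]) over the same residues.
#' @return A `fluct_profile` tibble with `kind = "delta_rmsd"`; values may
#'   be negative.
#' @export
delta_rmsd <- function(complex_profile, apo_profile) {
  a <- complex_profile; b <- apo_profile
  key <- if ("residue_id" %in% names(a)) "residue_id" else "atom_serial"
  if (!identical(a[[key]], b[[key]])) {
    off <- union(setdiff(a[[key]], b[[key]]), setdiff(b[[key]], a[[key]]))
    abort(sprintf("profiles do not align on %s: %s", key,
                  paste(off, collapse = ", ")))
  }
  out <- a[setdiff(names(a), c("value_nm", "kind"))]
  out$value_nm <- a$value_nm - b$value_nm
  .new_fluct_profile(out, "delta_rmsd")
}

#' Block standard error of a trajectory average
#'
#' Splits a per-frame series into `n_blocks` contiguous equal-length blocks
#' (any remainder frames at the end are dropped) and estimates the standard
#' error of the overall mean as `sd(block means) / sqrt(n_blocks)`, the
#' standard sub-trajectory scheme for correlated MD data.
#'
#' @param series Numeric vector of per-frame values.
#' @param n_blocks Number of blocks (default 3).
#' @return A list of class `block_error` with `mean`, `standard_error` and
#'   `n_blocks`.
#' @examples
#' block_standard_error(c(1, 1, 1, 2, 2, 2, 3, 3, 3))  # SE = 1/sqrt(3)
#' @export
block_standard_error <- function(series, n_blocks = 3L) {
  series <- as.numeric(series)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) abort("need at least 2 blocks")
  if (length(series) < n_blocks) abort("series shorter than the block count")
  len <- length(series) %/% n_blocks
  used <- series[seq_len(len * n_blocks)]
  bm <- colMeans(matrix(used, nrow = len))
  structure(list(mean = mean(series), standard_error = sd(bm) / sqrt(n_blocks),
                 n_blocks = n_blocks),
            class = "block_error")
}

#' @export
print.block_error <- function(x, ...) {
  cat(sprintf("mean %.6g +/- %.3g (block SE, %d blocks)\n",
              x$mean, x$standard_error, x$n_blocks))
  invisible(x)
}
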