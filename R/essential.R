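#' Positional-fluctuation covariance model (essential dynamics)
#'
#' Superposes the frames on their iterated mean over `selection`, builds the
#' mass-unweighted covariance matrix of the 3N atomic positional
#' fluctuations, `C = <(x - <x>)(x - <x>)'>` (time average over frames), and
#' diagonalises it. The eigenvectors are collective directions of motion;
#' each eigenvalue is the mean-square fluctuation (nm^2) along its
#' eigenvector, and the trace quantifies the total fluctuation.
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices (>= 2 atoms); `NULL` for all atoms.
#' @param fit Logical; superpose to the iterated mean first (default).
#'   Disable only for pre-fitted coordinates.
#' @return An object of class `covariance_model`: `mean_structure` (m x 3
#'   matrix, nm), `matrix` (3m x 3m, nm^2), `eigenvalues` (descending,
#'   values below 1e-12 clamped to 0), `eigenvectors` (orthonormal columns),
#'   `trace` (nm^2), `selection`, `n_frames`.
#' @export
build_covariance <- function(traj, selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- .as_selection(selection, traj)
  if (length(sel) < 2L) abort("selection must contain at least 2 atoms")
  if (n_frames(traj) < 2L) abort("need at least 2 frames")
  if (fit) {
    ft <- .fit_to_iterated_mean(traj$coords, sel)
    coords <- ft$coords
  } else {
    coords <- traj$coords
  }
  X <- .flatten_coords(coords[, sel, , drop = FALSE])
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(X) # time average, 1/n
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  ev <- e$values
  ev[abs(ev) < 1e-12] <- 0
  structure(list(
    mean_structure = matrix(mu, ncol = 3L, byrow = TRUE),
    matrix = C,
    eigenvalues = ev,
    eigenvectors = e$vectors,
    trace = sum(diag(C)),
    selection = sel,
    n_frames = nrow(X)
  ), class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> %d atoms, %d frames, trace %.4g nm^2\n",
              length(x$selection), x$n_frames, x$trace))
  cat("leading eigenvalues (nm^2):",
      paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project a trajectory onto an essential plane
#'
#' Each frame is superposed on the model's mean structure over the model's
#' selection and its deviation from the mean is projected onto the chosen
#' eigenvectors (by default the first two, the essential plane). For the
#' trajectory the model was built from, the variance of projection j equals
#' eigenvalue j.
#'
#' @param traj A [trajectory()] with the same atoms as the model's source.
#' @param model A [build_covariance()] fit.
#' @param k Pair of eigenvector indices, default `c(1, 2)`.
#' @return An `ed_projection` tibble with columns `frame`, `p1`, `p2` (nm);
#'   the eigenvector indices are kept in attribute `eigenvectors`.
#' @export
project_trajectory <- function(traj, model, k = c(1L, 2L)) {
  stopifnot(inherits(traj, "trajectory"), inherits(model, "covariance_model"))
  k <- as.integer(k)
  if (any(k < 1L) || any(k > ncol(model$eigenvectors))) {
    abort("eigenvector index out of range")
  }
  sel <- model$selection
  if (max(sel) > n_atoms(traj)) abort("model selection exceeds trajectory atoms")
  mu <- model$mean_structure
  nf <- n_frames(traj)
  P <- matrix(NA_real_, nf, length(k))
  V <- model$eigenvectors[, k, drop = FALSE]
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)[sel, , drop = FALSE]
    sp <- superpose(fr, mu, seq_len(nrow(fr)))
    d <- as.numeric(t(apply_superposition(fr, sp) - mu))
    P[f, ] <- crossprod(V, d)
  }
  out <- tibble(frame = seq_len(nf), p1 = P[, 1],
                p2 = if (ncol(P) > 1) P[, 2] else 0)
  attr(out, "eigenvectors") <- k
  class(out) <- c("ed_projection", class(out))
  out
}

#' Extract conformational basins from an essential-plane projection
#'
#' Bins the 2D projection on a square grid (extent = bounding box padded by
#' 5%), finds the `n_basins` highest local density maxima separated by at
#' least 2 grid cells (ties broken by lexicographic cell order), and for
#' each reports the occupied-cell centre, the fraction of frames nearer to
#' it than to any other basin centre, and the frame closest to the centre,
#' which serves as the basin's representative structure (e.g. a starting
#' configuration for free-energy calculations).
#'
#' Raw occupancy histograms of finite samples carry Poisson noise that
#' creates spurious local maxima; the histogram is therefore smoothed with a
#' 3x3 box filter (twice) before maxima detection, and candidate maxima
#' below `min_density` times the global smoothed maximum are discarded as
#' noise rather than counted as basins.
#'
#' @param projection An `ed_projection` from [project_trajectory()].
#' @param grid_bins Cells per axis (default 50).
#' @param n_basins Number of basins requested (>= 1). If fewer density
#'   maxima exist, the result carries attribute `underpopulated = TRUE` and
#'   a warning is raised.
#' @param min_density Relative density floor for a candidate maximum,
#'   as a fraction of the highest smoothed cell (default 0.2).
#' @return A tibble with columns `basin`, `center_p1`, `center_p2`,
#'   `population`, `representative_frame`; attribute `assignment` holds the
#'   per-frame basin index.
#' @export
extract_basins <- function(projection, grid_bins = 50L, n_basins = 1L,
                           min_density = 0.2) {
  stopifnot(inherits(projection, "ed_projection"), n_basins >= 1L)
  p1 <- projection$p1; p2 <- projection$p2
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- 1e-6
    r + c(-1, 1) * 0.05 * w
  }
  r1 <- pad(range(p1)); r2 <- pad(range(p2))
  b1 <- seq(r1[1], r1[2], length.out = grid_bins + 1L)
  b2 <- seq(r2[1], r2[2], length.out = grid_bins + 1L)
  i1 <- pmin(pmax(findInterval(p1, b1, all.inside = TRUE), 1L), grid_bins)
  i2 <- pmin(pmax(findInterval(p2, b2, all.inside = TRUE), 1L), grid_bins)
  H <- matrix(0, grid_bins, grid_bins)
  for (f in seq_along(p1)) H[i1[f], i2[f]] <- H[i1[f], i2[f]] + 1
  S <- .box_smooth(.box_smooth(H))
  # local maxima of the smoothed density over the 8-neighbourhood
  floor_d <- min_density * max(S)
  is_max <- matrix(FALSE, grid_bins, grid_bins)
  for (i in seq_len(grid_bins)) {
    for (j in seq_len(grid_bins)) {
      if (S[i, j] < floor_d || S[i, j] == 0) next
      nb <- S[max(1, i - 1):min(grid_bins, i + 1),
              max(1, j - 1):min(grid_bins, j + 1)]
      if (S[i, j] == max(nb)) is_max[i, j] <- TRUE
    }
  }
  cand <- which(is_max, arr.ind = TRUE)
  # order by density desc, ties by lexicographic (row, col)
  ord <- order(-S[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  picked <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(cand))) {
    if (nrow(picked) >= n_basins) break
    if (nrow(picked) == 0 ||
        all(pmax(abs(picked[, 1] - cand[r, 1]),
                 abs(picked[, 2] - cand[r, 2])) >= 2L)) {
      picked <- rbind(picked, cand[r, , drop = FALSE])
    }
  }
  found <- nrow(picked)
  if (found < n_basins) {
    warn(sprintf("requested %d basins but only %d density maxima found",
                 n_basins, found))
  }
  cx <- (b1[picked[, 1]] + b1[picked[, 1] + 1L]) / 2
  cy <- (b2[picked[, 2]] + b2[picked[, 2] + 1L]) / 2
  d2 <- outer(p1, cx, `-`)^2 + outer(p2, cy, `-`)^2
  assignment <- max.col(-d2, ties.method = "first")
  rep_frame <- vapply(seq_len(found), function(b) which.min(d2[, b]),
                      integer(1))
  out <- tibble(
    basin = seq_len(found),
    center_p1 = cx, center_p2 = cy,
    population = as.numeric(tabulate(assignment, found)) / length(p1),
    representative_frame = rep_frame)
  attr(out, "assignment") <- assignment
  attr(out, "underpopulated") <- found < n_basins
  out
}

# 3x3 box filter with edge-aware neighbour counts
.box_smooth <- function(H) {
  n <- nrow(H); m <- ncol(H)
  pad <- function(M) {
    P <- matrix(0, n + 2, m + 2)
    P[2:(n + 1), 2:(m + 1)] <- M
    P
  }
  acc <- function(P) {
    out <- matrix(0, n, m)
    for (di in 0:2) for (dj in 0:2) {
      out <- out + P[di + seq_len(n), dj + seq_len(m)]
    }
    out
  }
  acc(pad(H)) / acc(pad(matrix(1, n, m)))
}

#' Overlap of conformational spaces sampled by several trajectories
#'
#' All projections must be expressed on one common essential plane (build a
#' single covariance model on the concatenated trajectories, then project
#' each trajectory separately; see [concat_trajectories()]). Each projection
#' is binned on a shared 2D grid covering all points and the pairwise
#' overlap coefficient `sum_cells min(f_i, f_j)` of the normalised
#' histograms is returned: 1 for identically distributed clouds, 0 for
#' disjoint supports, intermediate for partial overlap of the sampled
#' conformational spaces.
#'
#' @param projections Named list of `ed_projection` tibbles on a common
#'   plane.
#' @param grid_bins Cells per axis (default 50).
#' @return Symmetric matrix of overlaps in `[0, 1]` with unit diagonal.
#' @export
compare_conformational_spaces <- function(projections, grid_bins = 50L) {
  if (!length(projections)) abort("no projections given")
  if (any(vapply(projections, nrow, integer(1)) == 0L)) {
    abort("empty projection")
  }
  allp1 <- unlist(lapply(projections, `[[`, "p1"))
  allp2 <- unlist(lapply(projections, `[[`, "p2"))
  pad <- function(r) r + c(-1, 1) * 0.05 * max(diff(r), 1e-6)
  r1 <- pad(range(allp1)); r2 <- pad(range(allp2))
  b1 <- seq(r1[1], r1[2], length.out = grid_bins + 1L)
  b2 <- seq(r2[1], r2[2], length.out = grid_bins + 1L)
  hist2 <- function(p) {
    i1 <- pmin(pmax(findInterval(p$p1, b1, all.inside = TRUE), 1L), grid_bins)
    i2 <- pmin(pmax(findInterval(p$p2, b2, all.inside = TRUE), 1L), grid_bins)
    H <- matrix(0, grid_bins, grid_bins)
    for (f in seq_len(nrow(p))) H[i1[f], i2[f]] <- H[i1[f], i2[f]] + 1
    H / nrow(p)
  }
  Hs <- lapply(projections, hist2)
  n <- length(Hs)
  M <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) M[i, j] <- M[j, i] <- sum(pmin(Hs[[i]], Hs[[j]]))
  }
  dimnames(M) <- list(names(projections), names(projections))
  M
}

#' Concatenate trajectories frame-wise
#'
#' Used to build one covariance model over several systems so that their
#' projections share an essential plane.
#'
#' @param ... [trajectory()] objects with identical atom counts.
#' @return A [trajectory()] with the frames of all inputs in order, atom
#'   metadata from the first.
#' @export
concat_trajectories <- function(...) {
  trs <- list(...)
  if (length(trs) == 1L && is.list(trs[[1]]) && !inherits(trs[[1]], "trajectory")) {
    trs <- trs[[1]]
  }
  stopifnot(all(vapply(trs, inherits, logical(1), "trajectory")))
  na <- unique(vapply(trs, n_atoms, integer(1)))
  if (length(na) != 1L) abort("trajectories differ in atom count")
  coords <- do.call(abind_frames, trs)
  trajectory(trs[[1]]$atoms, coords)
}

abind_frames <- function(...) {
  trs <- list(...)
  tot <- sum(vapply(trs, n_frames, integer(1)))
  na <- n_atoms(trs[[1]])
  out <- array(NA_real_, c(tot, na, 3L))
  at <- 1L
  for (tr in trs) {
    nf <- n_frames(tr)
    out[at:(at + nf - 1L), , ] <- tr$coords
    at <- at + nf
  }
  out
}
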