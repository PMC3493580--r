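#' Geometric hydrogen-bond criterion
#'
#' The default mirrors the widely used geometric rule from common MD
#' analysis tooling: donor-acceptor distance at most 0.35 nm and
#' hydrogen-donor-acceptor angle at most 30 degrees.
#'
#' @param max_da_distance Donor-acceptor cutoff, nm.
#' @param max_hda_angle Angle between the D-H and D-A vectors, degrees.
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 0.35, max_hda_angle = 30) {
  if (max_da_distance <= 0 || max_hda_angle <= 0) {
    abort("criterion parameters must be positive")
  }
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle),
            class = "hbond_criterion")
}

#' Count hydrogen bonds per frame
#'
#' A bond exists in a frame for a donor/hydrogen pair and an acceptor when
#' the donor-acceptor distance and the H-D-A angle both satisfy the
#' criterion. The per-frame count is the number of satisfying
#' (D, H, A) triples; the mean count carries a block standard error.
#'
#' @param traj A [trajectory()].
#' @param donors Two-column matrix (or list of length-2 vectors) of
#'   (donor, hydrogen) atom indices.
#' @param acceptors Vector of acceptor atom indices.
#' @param criterion An [hbond_criterion()].
#' @param n_blocks Blocks for the standard error of the mean count.
#' @return A tibble with columns `frame` and `count`; attribute
#'   `block_error` holds the [block_standard_error()] of the count series.
#' @export
hbond_count <- function(traj, donors, acceptors,
                        criterion = hbond_criterion(), n_blocks = 3L) {
  stopifnot(inherits(traj, "trajectory"), inherits(criterion, "hbond_criterion"))
  if (is.list(donors) && !is.matrix(donors)) donors <- do.call(rbind, donors)
  donors <- matrix(as.integer(donors), ncol = 2L)
  acceptors <- as.integer(acceptors)
  idx <- c(donors, acceptors)
  if (any(idx < 1L) || any(idx > n_atoms(traj))) abort("atom index out of range")
  cosmin <- cos(criterion$max_hda_angle * pi / 180)
  nf <- n_frames(traj)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    cnt <- 0L
    for (p in seq_len(nrow(donors))) {
      d <- fr[donors[p, 1], ]; h <- fr[donors[p, 2], ]
      dh <- h - d
      ndh <- sqrt(sum(dh^2))
      if (ndh < 1e-9) abort("hydrogen coincides with its donor")
      for (a in acceptors) {
        if (a == donors[p, 1]) next
        da <- fr[a, ] - d
        nda <- sqrt(sum(da^2))
        if (nda > criterion$max_da_distance) next
        if (sum(dh * da) / (ndh * nda) >= cosmin) cnt <- cnt + 1L
      }
    }
    counts[f] <- cnt
  }
  out <- tibble(frame = seq_len(nf), count = counts)
  if (nf >= n_blocks) {
    attr(out, "block_error") <- block_standard_error(counts, n_blocks)
  }
  out
}

#' Ring centre and least-squares plane normal
#'
#' The centre is the unweighted centroid of the ring atoms; the normal is
#' the smallest principal axis of their scatter (the least-squares plane
#' normal). The normal's sign is arbitrary; consumers take absolute dot
#' products.
#'
#' @param frame `n_atoms x 3` coordinate matrix (nm).
#' @param ring Integer vector of at least 3 atom indices.
#' @return A list with `center` (length 3, nm) and `normal` (unit length 3).
#' @export
ring_plane <- function(frame, ring) {
  ring <- as.integer(ring)
  if (length(ring) < 3L) abort("a ring needs at least 3 atoms")
  P <- as.matrix(frame)[ring, , drop = FALSE]
  ctr <- colMeans(P)
  S <- crossprod(sweep(P, 2, ctr))
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] < 1e-12 * max(e$values[1], 1e-300)) {
    abort("ring atoms are collinear; plane undefined")
  }
  list(center = ctr, normal = e$vectors[, 3])
}

#' Ring-stacking descriptors r, phi, psi along a trajectory
#'
#' For each frame, with ring centres `c_A`, `c_B` and least-squares plane
#' normals `n_A`, `n_B`:
#' * `r = |c_B - c_A|`, the centroid separation (nm);
#' * `phi = 90 - acos(|u . n_A|)` degrees, where `u` is the unit
#'   centroid-centroid vector: the elevation of `u` over ring A's plane, so
#'   two facing (stacked) rings give `phi = 90` and side-by-side coplanar
#'   rings give `phi = 0` - `phi` monitors the shifting of the stack;
#' * `psi = acos(|n_A . n_B|)` degrees, the angle between the ring planes:
#'   0 for perfect parallelism, 90 for perpendicular rings.
#'
#' `phi` is measured against the plane of `ring_a`, which should be the
#' reference (receptor-side) ring; swapping the rings leaves `r` and `psi`
#' unchanged.
#'
#' @param traj A [trajectory()].
#' @param ring_a,ring_b Atom index vectors of the two rings (`ring_a` =
#'   reference ring).
#' @return A `stacking_series` tibble with columns `frame`, `r_nm`,
#'   `phi_deg`, `psi_deg`.
#' @export
stacking_series <- function(traj, ring_a, ring_b) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  r <- phi <- psi <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    pa <- ring_plane(fr, ring_a)
    pb <- ring_plane(fr, ring_b)
    v <- pb$center - pa$center
    rr <- sqrt(sum(v^2))
    if (rr < 1e-6) abort(sprintf("coincident ring centres in frame %d", f))
    u <- v / rr
    clamp <- function(x) pmin(pmax(x, -1), 1)
    r[f] <- rr
    phi[f] <- 90 - acos(clamp(abs(sum(u * pa$normal)))) * 180 / pi
    psi[f] <- acos(clamp(abs(sum(pa$normal * pb$normal)))) * 180 / pi
  }
  out <- tibble(frame = seq_len(nf), r_nm = r, phi_deg = phi, psi_deg = psi)
  class(out) <- c("stacking_series", class(out))
  out
}

#' Fraction of frames in which a stacking interaction is formed
#'
#' A frame counts as "formed" when `r <= r_max`, `phi >= phi_min` and
#' `psi <= psi_max` simultaneously. The default box (0.55 nm, 60 deg,
#' 30 deg) is a package choice delimiting near-face-to-face, near-parallel
#' geometries; tune it to the system and report it alongside results (it is
#' attached as attribute `thresholds`).
#'
#' @param series A `stacking_series` from [stacking_series()].
#' @param r_max Maximum centroid distance, nm.
#' @param phi_min Minimum elevation angle, degrees.
#' @param psi_max Maximum inter-plane angle, degrees.
#' @return Fraction of frames formed, with attribute `thresholds`.
#' @export
stacking_occupancy <- function(series, r_max = 0.55, phi_min = 60,
                               psi_max = 30) {
  stopifnot(nrow(series) > 0)
  formed <- series$r_nm <= r_max & series$phi_deg >= phi_min &
    series$psi_deg <= psi_max
  structure(mean(formed),
            thresholds = list(r_max = r_max, phi_min = phi_min,
                              psi_max = psi_max))
}
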