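#' Random internal fluctuation modes for the Gaussian generator
#'
#' Draws `k` mutually orthonormal directions in the 3N-dimensional
#' configuration space of `n_atoms` atoms, orthogonalised against the six
#' rigid-body degrees of freedom of the reference structure so that planted
#' motion is purely internal (as collective modes of a real molecule are).
#'
#' @param n_atoms Number of atoms.
#' @param k Number of modes.
#' @param mean_structure Optional `n_atoms x 3` reference (nm); defaults to
#'   the generator's own seeded mean structure.
#' @param seed Integer seed.
#' @return `3*n_atoms x k` matrix with orthonormal columns.
#' @export
random_internal_modes <- function(n_atoms, k, mean_structure = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(mean_structure)) mean_structure <- .seeded_mean_structure(n_atoms)
  n3 <- 3L * n_atoms
  if (k > n3 - 6L) abort("too many modes for the internal subspace")
  raw <- matrix(rnorm(n3 * k), n3, k)
  rb <- .rigid_body_basis(mean_structure)
  raw <- raw - rb %*% crossprod(rb, raw)
  qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
}

# Orthonormal basis of the 6 rigid-body dof (3 translations, 3 infinitesimal
# rotations about the centroid) at a reference structure.
.rigid_body_basis <- function(ref) {
  n <- nrow(ref)
  ctr <- sweep(ref, 2, colMeans(ref))
  B <- matrix(0, 3L * n, 6L)
  for (k in 1:3) B[seq(k, 3L * n, by = 3L) + 0, k] <- 1
  # rotation about axis e_a: displacement e_a x r_i
  ax <- diag(3)
  for (a in 1:3) {
    d <- t(apply(ctr, 1, function(r) c(ax[a, 2] * r[3] - ax[a, 3] * r[2],
                                       ax[a, 3] * r[1] - ax[a, 1] * r[3],
                                       ax[a, 1] * r[2] - ax[a, 2] * r[1])))
    B[, 3 + a] <- as.numeric(t(d))
  }
  qr.Q(qr(B))
}

# Deterministic compact random-globule mean structure (nm); depends only on
# the current RNG state.
.seeded_mean_structure <- function(n_atoms) {
  matrix(rnorm(3 * n_atoms, sd = 0.5), n_atoms, 3L)
}

.default_atoms <- function(n_atoms) {
  tibble(serial = seq_len(n_atoms), name = "CA", residue_name = "GLY",
         residue_id = seq_len(n_atoms), chain = "A", element = "C")
}

# flatten frames x atoms x 3 <-> frames x 3N (atom-major triples x,y,z)
.flatten_coords <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  m <- matrix(NA_real_, nf, 3L * na)
  for (k in 1:3) m[, seq(k, 3L * na, by = 3L)] <- coords[, , k]
  m
}

.unflatten_coords <- function(m) {
  nf <- nrow(m); na <- ncol(m) / 3L
  coords <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) coords[, , k] <- m[, seq(k, 3L * na, by = 3L), drop = FALSE]
  coords
}

#' Gaussian trajectory with planted low-rank covariance
#'
#' Frames are drawn as `mean + sum_k a_k v_k + noise` with amplitudes
#' `a_k ~ Normal(0, variance_k)` along orthonormal internal directions `v_k`
#' and isotropic Gaussian noise of per-coordinate variance `iso_noise`. The
#' population covariance is therefore `sum_k variance_k v_k v_k' +
#' iso_noise I`, so essential-dynamics analysis has an exact oracle: its top
#' eigenvalues should approach `variance_k + iso_noise` and its eigenvectors
#' the planted directions.
#'
#' @param n_atoms Number of atoms.
#' @param modes List of planted modes, each `list(direction = <unit 3N
#'   vector>, variance = <nm^2>)`; directions must be mutually orthogonal.
#'   `NULL` for pure isotropic noise.
#' @param iso_noise Per-coordinate noise variance (nm^2).
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A [trajectory()].
#' @export
gen_gaussian_traj <- function(n_atoms, modes = NULL, iso_noise = 0,
                              n_frames = 1000L, seed = 1L) {
  if (n_frames < 2L) abort("need at least 2 frames")
  if (iso_noise < 0) abort("`iso_noise` must be non-negative")
  set.seed(seed)
  mean_structure <- .seeded_mean_structure(n_atoms)
  n3 <- 3L * n_atoms
  V <- NULL; vars <- numeric(0)
  if (!is.null(modes) && length(modes)) {
    V <- vapply(modes, function(m) as.numeric(m$direction), numeric(n3))
    vars <- vapply(modes, function(m) as.numeric(m$variance), numeric(1))
    if (any(vars < 0)) abort("mode variances must be non-negative")
    nrm <- sqrt(colSums(V^2))
    if (any(abs(nrm - 1) > 1e-8)) abort("mode directions must be unit vectors")
    G <- crossprod(V)
    if (max(abs(G - diag(ncol(V)))) > 1e-8) {
      abort("mode directions must be mutually orthogonal")
    }
  }
  flat_mean <- as.numeric(t(mean_structure))
  X <- matrix(rep(flat_mean, each = n_frames), n_frames, n3)
  if (!is.null(V)) {
    amp <- matrix(rnorm(n_frames * ncol(V)), n_frames) %*%
      diag(sqrt(vars), ncol(V))
    X <- X + amp %*% t(V)
  }
  if (iso_noise > 0) {
    X <- X + matrix(rnorm(n_frames * n3, sd = sqrt(iso_noise)), n_frames)
  }
  trajectory(.default_atoms(n_atoms), .unflatten_coords(X))
}

#' Two-state (open/closed) trajectory with known frame labels
#'
#' Emulates a loop exchanging between two conformational basins: frames are
#' drawn around two centres separated by `displacement`, with isotropic
#' Gaussian jitter, and the per-frame state labels are returned so basin
#' extraction can be scored against the truth without a clustering oracle.
#'
#' @param n_atoms Number of atoms.
#' @param displacement Length-`3*n_atoms` displacement vector between the
#'   two centres (nm), or a single number applied along the first
#'   coordinate of atom 1.
#' @param open_fraction Expected fraction of frames in the open state,
#'   strictly between 0 and 1.
#' @param n_frames Number of frames.
#' @param jitter Per-coordinate jitter variance (nm^2).
#' @param seed Integer seed.
#' @return A list with elements `trajectory` and `labels` (character,
#'   `"open"`/`"closed"`).
#' @export
gen_two_state_loop <- function(n_atoms, displacement, open_fraction = 0.5,
                               n_frames = 1000L, jitter = 1e-4, seed = 1L) {
  if (open_fraction <= 0 || open_fraction >= 1) {
    abort("`open_fraction` must be strictly between 0 and 1")
  }
  n3 <- 3L * n_atoms
  if (length(displacement) == 1L) {
    displacement <- c(displacement, rep(0, n3 - 1L))
  }
  displacement <- as.numeric(displacement)
  if (length(displacement) != n3) abort("`displacement` must have length 3*n_atoms")
  if (sqrt(sum(displacement^2)) < 1e-12) {
    abort("zero displacement cannot produce two basins")
  }
  set.seed(seed)
  mean_structure <- .seeded_mean_structure(n_atoms)
  flat_mean <- as.numeric(t(mean_structure))
  open <- rbinom(n_frames, 1L, open_fraction) == 1L
  X <- matrix(rep(flat_mean, each = n_frames), n_frames, n3)
  X <- X + outer(ifelse(open, 0.5, -0.5), displacement)
  if (jitter > 0) {
    X <- X + matrix(rnorm(n_frames * n3, sd = sqrt(jitter)), n_frames)
  }
  list(trajectory = trajectory(.default_atoms(n_atoms), .unflatten_coords(X)),
       labels = ifelse(open, "open", "closed"))
}

# Regular planar ring template centred at the origin in the xy-plane.
# side lengths chosen to mimic six-membered aromatic (0.14 nm) and
# five-membered (0.137 nm) rings.
.ring_template <- function(n_vertices = 6L) {
  side <- if (n_vertices == 6L) 0.14 else 0.137
  radius <- side / (2 * sin(pi / n_vertices))
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  cbind(radius * cos(th), radius * sin(th), 0)
}

#' Ring-pair trajectory with a prescribed stacking schedule
#'
#' Generates two rigid planar rings whose per-frame centroid distance `r`,
#' elevation angle `phi` of the centroid-centroid vector over the first
#' ring's plane, and inter-normal angle `psi` follow the given schedule
#' exactly, providing a closed-form oracle for [stacking_series()]. Ring A
#' (the reference ring, e.g. a histidine imidazole) stays fixed in the
#' xy-plane; ring B is placed at elevation `phi` and tilted by `psi`.
#'
#' @param schedule Data frame with columns `r` (nm, > 0), `phi` and `psi`
#'   (degrees, in `[0, 90]`), one row per frame.
#' @param ring_b_vertices 6 (default) or 5, the second ring's size.
#' @return A [trajectory()] whose first `ring_a_vertices` atoms are ring A
#'   (residue `RGA`) and the rest ring B (residue `RGB`).
#' @export
gen_ring_pair_series <- function(schedule, ring_b_vertices = 6L) {
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("r", "phi", "psi") %in% names(schedule)))
  if (any(schedule$r <= 0)) abort("scheduled `r` must be positive")
  if (any(schedule$phi < 0 | schedule$phi > 90)) abort("`phi` must be in [0, 90]")
  if (any(schedule$psi < 0 | schedule$psi > 90)) abort("`psi` must be in [0, 90]")
  ring_a <- .ring_template(6L)
  ring_b0 <- .ring_template(ring_b_vertices)
  na <- nrow(ring_a); nb <- nrow(ring_b0)
  nf <- nrow(schedule)
  coords <- array(NA_real_, c(nf, na + nb, 3L))
  for (f in seq_len(nf)) {
    phi <- schedule$phi[f] * pi / 180
    psi <- schedule$psi[f] * pi / 180
    centre_b <- schedule$r[f] * c(cos(phi), 0, sin(phi))
    # tilt ring B's normal from z by psi about the y axis
    Ry <- rbind(c(cos(psi), 0, sin(psi)), c(0, 1, 0), c(-sin(psi), 0, cos(psi)))
    ring_b <- sweep(ring_b0 %*% t(Ry), 2, centre_b, `+`)
    coords[f, , ] <- rbind(ring_a, ring_b)
  }
  atoms <- tibble(
    serial = seq_len(na + nb),
    name = c(sprintf("A%d", seq_len(na)), sprintf("B%d", seq_len(nb))),
    residue_name = rep(c("RGA", "RGB"), c(na, nb)),
    residue_id = rep(c(1L, 2L), c(na, nb)),
    chain = "A", element = "C")
  trajectory(atoms, coords)
}

#' Donor-hydrogen-acceptor trajectory with planted hydrogen-bond occupancy
#'
#' In an `occupancy` fraction of frames (Bernoulli draws) the three atoms
#' satisfy the default geometric hydrogen-bond criterion with a comfortable
#' margin (donor-acceptor 0.28 nm, linear); in the rest the donor-acceptor
#' distance is 0.42 nm, at least 0.05 nm beyond the default cutoff.
#'
#' @param occupancy Target fraction of frames with the bond formed, in
#'   `[0, 1]`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A list with `trajectory` (atoms D, H, A in that order) and
#'   `formed` (logical per frame).
#' @export
gen_hbond_series <- function(occupancy, n_frames = 1000L, seed = 1L) {
  if (occupancy < 0 || occupancy > 1) abort("`occupancy` must be in [0, 1]")
  set.seed(seed)
  formed <- if (occupancy == 0) rep(FALSE, n_frames)
            else if (occupancy == 1) rep(TRUE, n_frames)
            else rbinom(n_frames, 1L, occupancy) == 1L
  coords <- array(0, c(n_frames, 3L, 3L))
  coords[, 2, 1] <- 0.10                       # hydrogen on the D->A axis
  coords[, 3, 1] <- ifelse(formed, 0.28, 0.42) # acceptor distance
  atoms <- tibble(serial = 1:3, name = c("N", "H", "O"),
                  residue_name = c("DON", "DON", "ACC"),
                  residue_id = c(1L, 1L, 2L), chain = "A",
                  element = c("N", "H", "O"))
  list(trajectory = trajectory(atoms, coords), formed = formed)
}

#' Thermodynamic-integration samples from a harmonic model with known answer
#'
#' The alchemical path couples two harmonic wells linearly,
#' `k(lambda) = (1 - lambda) k1 + lambda k2`, so the coupling derivative is
#' `dH/dlambda = (k2 - k1) x^2 / 2` with `x ~ Normal(0, RT / k(lambda))` at
#' equilibrium. The free-energy difference has the closed form
#' `Delta F = (RT / 2) ln(k2 / k1)`, giving thermodynamic-integration
#' quadrature an exact oracle.
#'
#' @param k1,k2 Endpoint force constants, kJ/(mol nm^2), both positive.
#' @param temperature Temperature in K.
#' @param lambdas Strictly increasing grid spanning `[0, 1]`.
#' @param n_per_lambda Samples per grid point (>= 2).
#' @param seed Integer seed.
#' @return A [ti_profile()] with attribute `true_delta_f` (kJ/mol).
#' @export
gen_ti_samples <- function(k1, k2, temperature = 300,
                           lambdas = seq(0, 1, length.out = 21L),
                           n_per_lambda = 1000L, seed = 1L) {
  if (k1 <= 0 || k2 <= 0) abort("force constants must be positive")
  if (length(lambdas) < 2L || lambdas[1] != 0 || lambdas[length(lambdas)] != 1 ||
      any(diff(lambdas) <= 0)) {
    abort("`lambdas` must be strictly increasing and span [0, 1]")
  }
  if (n_per_lambda < 2L) abort("need at least 2 samples per lambda")
  set.seed(seed)
  rt <- .R_GAS * temperature
  samples <- lapply(lambdas, function(l) {
    k <- (1 - l) * k1 + l * k2
    x <- rnorm(n_per_lambda, sd = sqrt(rt / k))
    0.5 * (k2 - k1) * x^2
  })
  prof <- ti_profile(lambdas, samples, temperature = temperature)
  attr(prof, "true_delta_f") <- rt / 2 * log(k2 / k1)
  prof
}
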