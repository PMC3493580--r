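RT300 <- 8.314462618e-3 * 300

# small peptide-like trajectory: n_res residues, CA + CB per residue,
# replicated reference frame unless coords supplied
make_peptide_traj <- function(n_res = 5, n_frames = 3, coords = NULL) {
  atoms <- data.frame(
    serial = seq_len(2 * n_res),
    name = rep(c("CA", "CB"), n_res),
    residue_name = "ALA",
    residue_id = rep(seq_len(n_res), each = 2),
    chain = "A",
    element = "C")
  if (is.null(coords)) {
    ref <- cbind(seq_len(2 * n_res) * 0.15,
                 rep(c(0, 0.1), n_res),
                 rep(c(0, 0.05), n_res))
    coords <- array(rep(ref, each = n_frames), c(n_frames, 2 * n_res, 3))
  }
  trajectory(atoms, coords)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_move <- function(traj, R = random_rotation(), t = rnorm(3)) {
  coords <- traj$coords
  for (f in seq_len(dim(coords)[1])) {
    coords[f, , ] <- sweep(matrix(coords[f, , ], ncol = 3) %*% t(R), 2, t, `+`)
  }
  trajectory(traj$atoms, coords, times = traj$times)
}

# fabricate an essential-plane projection from bare coordinates
as_projection <- function(p1, p2) {
  out <- tibble::tibble(frame = seq_along(p1), p1 = p1, p2 = p2)
  attr(out, "eigenvectors") <- c(1L, 2L)
  class(out) <- c("ed_projection", class(out))
  out
}
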