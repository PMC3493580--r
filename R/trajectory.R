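#' Build a trajectory object
#'
#' A trajectory couples an atom table with a `frames x atoms x 3` coordinate
#' array in nanometres. It is the common input of all fluctuation,
#' essential-dynamics and interaction analyses in the package.
#'
#' @param atoms Data frame with one row per atom and columns `serial`,
#'   `name`, `residue_name`, `residue_id`, `chain`, `element`. Missing
#'   metadata columns are filled with defaults.
#' @param coords Numeric array of dimension `c(n_frames, n_atoms, 3)` (or an
#'   `n_atoms x 3` matrix for a single frame), in nm.
#' @param times Optional per-frame times in ps, strictly increasing.
#'
#' @return An object of class `trajectory` with elements `atoms` (tibble),
#'   `coords` (array) and `times`.
#' @examples
#' atoms <- data.frame(serial = 1:2, name = "CA", residue_name = "ALA",
#'                     residue_id = 1:2, chain = "A", element = "C")
#' xyz <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
#' trj <- trajectory(atoms, xyz)
#' n_frames(trj)
#' @export
trajectory <- function(atoms, coords, times = NULL) {
  atoms <- as_tibble(as.data.frame(atoms))
  defaults <- list(name = "CA", residue_name = "ALA", chain = "A", element = "C")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$residue_id)) atoms$residue_id <- seq_len(nrow(atoms))
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  atoms <- atoms[, c("serial", "name", "residue_name", "residue_id",
                     "chain", "element")]
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("`coords` must be a frames x atoms x 3 array.")
  }
  if (dim(coords)[2] != nrow(atoms)) {
    abort(sprintf("coordinate array has %d atoms but atom table has %d rows",
                  dim(coords)[2], nrow(atoms)))
  }
  if (dim(coords)[1] < 1L) abort("a trajectory needs at least one frame")
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (anyDuplicated(atoms$serial)) abort("atom serials must be unique")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != dim(coords)[1]) {
      abort("`times` must have one entry per frame")
    }
    if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  }
  structure(list(atoms = atoms, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, %d residues\n",
              n_frames(x), n_atoms(x),
              length(unique(paste(x$atoms$chain, x$atoms$residue_id)))))
  invisible(x)
}

#' Trajectory dimensions
#' @param traj A [trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an atoms x 3 coordinate matrix (nm)
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) abort("frame index out of range")
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a bare `ATOM` block with no
#' `MODEL` keyword is a single frame. Coordinates are converted from the PDB's
#' Angstrom convention to nm. Atom metadata is taken from the first model; all
#' models must contain the same atoms in the same order.
#'
#' @param path Path to a PDB file.
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(sprintf("failed to parse PDB '%s': %s",
                                      path, conditionMessage(e)))
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nat <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * nat) {
    abort("atom count differs between models in multi-model PDB")
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, nat, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * nat, by = 3L), drop = FALSE]
  coords <- coords / 10 # Angstrom -> nm
  atoms <- tibble(
    serial = as.integer(pdb$atom$eleno),
    name = trimws(pdb$atom$elety),
    residue_name = trimws(pdb$atom$resid),
    residue_id = as.integer(pdb$atom$resno),
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    element = trimws(ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                            substr(trimws(pdb$atom$elety), 1, 1),
                            pdb$atom$elesy))
  )
  times <- .parse_time_remarks(path, nf)
  trajectory(atoms, coords, times = times)
}

.parse_time_remarks <- function(path, nf) {
  ln <- grep("^REMARK +TIME_PS", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) != nf) return(NULL)
  t <- suppressWarnings(as.numeric(sub("^REMARK +TIME_PS +", "", ln)))
  if (anyNA(t) || any(diff(t) <= 0)) return(NULL)
  t
}

#' Write a trajectory to a multi-model PDB file
#'
#' Coordinates are converted nm to Angstrom and written at the PDB's
#' three-decimal precision, so a read/write round trip preserves coordinates
#' to 1e-4 nm. Frame times, when present, are stored in `REMARK TIME_PS`
#' records that [read_multimodel_pdb()] recovers.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$times)) {
    writeLines(sprintf("REMARK TIME_PS %.4f", traj$times), con)
  }
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f) * 10 # nm -> Angstrom
    name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                    sprintf("%-4s", a$name))
    lines <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, name4, "", substr(a$residue_name, 1, 3),
      substr(a$chain, 1, 1), a$residue_id %% 10000L, "",
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, substr(a$element, 1, 2))
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by name, residue and chain
#'
#' Criteria are combined with AND; a criterion left `NULL` matches
#' everything. The result preserves atom order and may be empty.
#'
#' @param traj A [trajectory()].
#' @param name Atom name(s), e.g. `"CA"`.
#' @param residue_id Residue id(s); ranges as vectors, e.g. `223:234`.
#' @param chain Chain identifier(s).
#' @param residue_name Residue name(s).
#' @param element Element symbol(s).
#' @return Integer vector of atom indices (1-based into the atom table),
#'   with class `atom_selection`.
#' @examples
#' \dontrun{
#' loop_ca <- select_atoms(trj, name = "CA", residue_id = 223:234)
#' }
#' @export
select_atoms <- function(traj, name = NULL, residue_id = NULL, chain = NULL,
                         residue_name = NULL, element = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  crit <- list(name = name, residue_id = residue_id, chain = chain,
               residue_name = residue_name, element = element)
  cols <- c(name = "name", residue_id = "residue_id", chain = "chain",
            residue_name = "residue_name", element = "element")
  for (nm in names(crit)) {
    v <- crit[[nm]]
    if (is.null(v)) next
    if (length(v) == 0) abort(sprintf("selection criterion `%s` is empty", nm))
    keep <- keep & (a[[cols[[nm]]]] %in% v)
  }
  structure(which(keep), class = "atom_selection")
}

.as_selection <- function(sel, traj) {
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  sel <- as.integer(sel)
  if (anyDuplicated(sel)) abort("selection indices must be unique")
  if (length(sel) && (min(sel) < 1L || max(sel) > n_atoms(traj))) {
    abort("selection index out of range")
  }
  sel
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the unweighted sum of
#' squared deviations between `mobile` and `reference` over the fit atoms.
#' Reflections are excluded by the usual determinant correction, so chiral
#' structures are never mirrored.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices (nm).
#' @param fit_selection Atom indices used for the fit (default: all).
#' @return A list of class `superposition` with elements `rotation` (3x3,
#'   `det = +1`), `translation` (length-3, nm) and `rmsd` (nm, over the fit
#'   atoms after transformation). Apply with [apply_superposition()].
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    abort("`mobile` and `reference` must have the same dimensions")
  }
  sel <- if (is.null(fit_selection)) seq_len(nrow(mobile)) else as.integer(fit_selection)
  if (length(sel) < 3L) abort("need at least 3 fit atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    abort("degenerate fit: fewer than 3 non-collinear fit atoms")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to a coordinate matrix
#' @param coords `n x 3` matrix (nm).
#' @param sp A `superposition` from [superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, `+`)
}

# RMSD between two frames over a set of atoms, no fitting.
.frame_rmsd <- function(a, b, sel) {
  d <- a[sel, , drop = FALSE] - b[sel, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

# Superpose every frame onto `reference` over `fit_sel`; returns the
# transformed coordinate array.
.fit_frames <- function(coords, reference, fit_sel) {
  nf <- dim(coords)[1]
  out <- coords
  for (f in seq_len(nf)) {
    fr <- matrix(coords[f, , ], ncol = 3L)
    sp <- superpose(fr, reference, fit_sel)
    out[f, , ] <- apply_superposition(fr, sp)
  }
  out
}

# Iterated fit-to-mean: superpose all frames on the running mean structure
# over `fit_sel` until the mean moves by < tol (max abs coordinate change),
# the standard pre-processing for RMSF and covariance analysis.
.fit_to_iterated_mean <- function(coords, fit_sel, tol = 1e-9, max_iter = 10L) {
  ref <- matrix(coords[1, , ], ncol = 3L)
  fitted <- coords
  for (it in seq_len(max_iter)) {
    fitted <- .fit_frames(coords, ref, fit_sel)
    m <- apply(fitted, c(2, 3), mean)
    if (max(abs(m - ref)) < tol) {
      ref <- m
      break
    }
    ref <- m
  }
  list(coords = fitted, mean = ref)
}
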