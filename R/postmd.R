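#' Standard atomic masses
#' @param element character vector of element symbols.
#' @return numeric vector (g/mol).
#' @export
atomic_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
           Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45,
           K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
           Br = 79.904, I = 126.904, Mo = 95.95)
  m <- tab[element]
  if (anyNA(m)) stop("no mass for element(s): ",
                     paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Binding free energy by end-point subtraction
#'
#' `dG_bind = G_complex - G_free_protein - G_free_ligand` (kJ/mol).
#'
#' @param complex_g,protein_g,ligand_g free energies in kJ/mol.
#' @return binding free energy, kJ/mol.
#' @export
binding_energy <- function(complex_g, protein_g, ligand_g) {
  complex_g - protein_g - ligand_g
}

#' Aggregate MM-PBSA energy components
#'
#' The binding free energy decomposes into van der Waals, electrostatic,
#' polar-solvation (Poisson-Boltzmann) and nonpolar surface-area terms;
#' their sum is the total.
#'
#' @param e_vdw,e_ele,g_pb,g_sa component means, kJ/mol (vectorized).
#' @return g_binding, kJ/mol.
#' @export
aggregate_components <- function(e_vdw, e_ele, g_pb, g_sa) {
  e_vdw + e_ele + g_pb + g_sa
}

#' Read an MM-PBSA component table
#'
#' CSV with columns `complex`, `e_vdw`, `e_ele`, `g_pb`, `g_sa` and
#' optionally `g_binding` (checked against the component sum when present,
#' tolerance 0.01 kJ/mol).
#'
#' @param path CSV path (defaults to the packaged reference table).
#' @return data.frame with a recomputed `g_binding_sum` column.
#' @export
read_energy_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mmpbsa_energies.csv", package = "xoiqsar")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex", "e_vdw", "e_ele", "g_pb", "g_sa")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("energy table missing columns: ",
                            paste(missing, collapse = ", "))
  d$g_binding_sum <- aggregate_components(d$e_vdw, d$e_ele, d$g_pb, d$g_sa)
  if ("g_binding" %in% names(d)) {
    off <- which(abs(d$g_binding - d$g_binding_sum) > 0.01)
    if (length(off)) warning("component sums disagree with stated totals for: ",
                             paste(d$complex[off], collapse = ", "))
  }
  d
}

#' Construct a trajectory object
#'
#' @param coords numeric array n_frames x n_atoms x 3 (nm), or a list of
#'   n_atoms x 3 frame matrices.
#' @param element optional element symbols (length n_atoms).
#' @param resid optional residue indices per atom.
#' @param mass optional masses; derived from elements when absent.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, element = NULL, resid = NULL, mass = NULL) {
  if (is.list(coords)) {
    na <- nrow(coords[[1]])
    if (any(vapply(coords, nrow, 1L) != na)) {
      stop("all frames must have the same atom count")
    }
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_atoms <- dim(coords)[2]
  if (!is.null(mass) && any(mass <= 0)) stop("masses must be positive")
  if (is.null(mass) && !is.null(element)) mass <- atomic_mass(element)
  structure(list(coords = coords, element = element,
                 resid = resid %||% seq_len(n_atoms), mass = mass),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames x %d atoms>\n",
              dim(x$coords)[1], dim(x$coords)[2]))
  invisible(x)
}

#' @keywords internal
get_frame <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' RMSD after optimal (Kabsch) superposition
#'
#' Superposes the masked atoms of `frame` onto `reference` with the
#' least-squares proper rotation and reports the root-mean-square
#' deviation of the masked atoms.
#'
#' @param frame,reference n x 3 coordinate matrices (same units in = out).
#' @param mask optional integer/logical atom selection.
#' @return RMSD in the input units.
#' @export
kabsch_rmsd <- function(frame, reference, mask = NULL) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  if (!is.null(mask)) {
    frame <- frame[mask, , drop = FALSE]
    reference <- reference[mask, , drop = FALSE]
  }
  kabsch(frame, reference)$rmsd
}

#' Per-frame RMSD series of a trajectory
#'
#' @param traj a [trajectory()].
#' @param reference frame index used as reference (default 1) or an
#'   n x 3 matrix.
#' @param mask optional atom selection.
#' @return numeric vector, one RMSD per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, mask = NULL) {
  ref <- if (is.matrix(reference)) reference else get_frame(traj, reference)
  vapply(seq_len(dim(traj$coords)[1]),
         function(i) kabsch_rmsd(get_frame(traj, i), ref, mask), numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the time-average structure (two alignment
#' passes: first onto a provisional reference frame, then onto the
#' resulting mean), the per-atom RMS deviation about the final mean is
#' computed, and atoms are averaged within residues. Residues exceeding
#' `flex_threshold` are flagged as highly flexible.
#'
#' @param traj a [trajectory()].
#' @param mask optional atom selection used for the superposition.
#' @param flex_threshold flexibility flag threshold, same units as the
#'   coordinates (default 0.35, i.e. nm for nm trajectories).
#' @return list with `rmsf_per_atom`, `rmsf_per_residue` (named by residue
#'   index), `high_flex_residues`.
#' @export
rmsf <- function(traj, mask = NULL, flex_threshold = 0.35) {
  nf <- dim(traj$coords)[1]
  frames <- lapply(seq_len(nf), function(i) get_frame(traj, i))
  align_all <- function(frames, ref) {
    lapply(frames, function(fr) {
      sel <- if (is.null(mask)) seq_len(nrow(fr)) else mask
      kabsch(fr[sel, , drop = FALSE], ref[sel, , drop = FALSE])$transform(fr)
    })
  }
  aligned <- align_all(frames, frames[[1]])
  mean_xyz <- Reduce(`+`, aligned) / nf
  aligned <- align_all(aligned, mean_xyz)
  mean_xyz <- Reduce(`+`, aligned) / nf
  dev2 <- Reduce(`+`, lapply(aligned, function(fr) rowSums((fr - mean_xyz)^2)))
  per_atom <- sqrt(dev2 / nf)
  per_res <- vapply(split(per_atom, traj$resid), mean, numeric(1))
  per_res <- per_res[order(as.numeric(names(per_res)))]
  list(rmsf_per_atom = per_atom, rmsf_per_residue = per_res,
       high_flex_residues = as.numeric(names(per_res))[per_res > flex_threshold])
}

#' Mass-weighted radius of gyration of one frame
#'
#' `sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`; unit masses when none are
#' given.
#'
#' @param frame n x 3 coordinate matrix.
#' @param masses optional positive weights.
#' @return Rg in the coordinate units.
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  frame <- as.matrix(frame)
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  stopifnot(length(masses) == nrow(frame))
  if (any(masses <= 0)) stop("masses must be positive")
  com <- colSums(frame * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(frame, 2, com)^2)) / sum(masses))
}

#' Radius-of-gyration series over a trajectory
#' @param traj a [trajectory()].
#' @return numeric vector, one Rg per frame.
#' @export
rg_series <- function(traj) {
  vapply(seq_len(dim(traj$coords)[1]),
         function(i) radius_of_gyration(get_frame(traj, i), traj$mass),
         numeric(1))
}

#' Geometric hydrogen-bond count in one frame
#'
#' Counts donor-H...acceptor triples with donor-acceptor distance at most
#' `d_cut` and donor-H-acceptor angle (vertex at H) at least `angle_cut`.
#'
#' @param frame n x 3 coordinate matrix.
#' @param donors 2-column integer matrix of (donor heavy atom, its H) rows.
#' @param acceptors integer vector of acceptor atom indices.
#' @param d_cut distance cutoff in the coordinate units (default 0.35,
#'   i.e. nm).
#' @param angle_cut angle cutoff in degrees (default 120).
#' @return integer count.
#' @export
hbond_count <- function(frame, donors, acceptors, d_cut = 0.35,
                        angle_cut = 120) {
  frame <- as.matrix(frame)
  donors <- matrix(as.integer(donors), ncol = 2)
  count <- 0L
  for (r in seq_len(nrow(donors))) {
    d <- donors[r, 1]; h <- donors[r, 2]
    for (a in acceptors) {
      if (a == d) next
      da <- sqrt(sum((frame[a, ] - frame[d, ])^2))
      if (da > d_cut) next
      v1 <- frame[d, ] - frame[h, ]; v2 <- frame[a, ] - frame[h, ]
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= angle_cut) count <- count + 1L
    }
  }
  count
}

#' Hydrogen-bond count series over a trajectory
#' @inheritParams hbond_count
#' @param traj a [trajectory()].
#' @return integer vector, one count per frame.
#' @export
hbond_series <- function(traj, donors, acceptors, d_cut = 0.35,
                         angle_cut = 120) {
  vapply(seq_len(dim(traj$coords)[1]), function(i) {
    hbond_count(get_frame(traj, i), donors, acceptors, d_cut, angle_cut)
  }, integer(1))
}

#' Read / write multi-frame XYZ trajectories
#'
#' Plain XYZ: per frame an atom count line, a comment line, then
#' `element x y z` rows. Coordinates are taken as-is; pass `scale` to
#' convert on read (e.g. 0.1 for Angstrom files feeding nm pipelines).
#'
#' @param path file path.
#' @param scale multiplicative coordinate conversion on read.
#' @return [read_xyz_trajectory()] returns a [trajectory()].
#' @export
read_xyz_trajectory <- function(path, scale = 1) {
  lines <- readLines(path)
  frames <- list(); elements <- NULL; i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) * scale
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  trajectory(frames, element = elements)
}

#' @rdname read_xyz_trajectory
#' @param traj a [trajectory()] (elements required).
#' @export
write_xyz_trajectory <- function(traj, path) {
  el <- traj$element %||% rep("X", dim(traj$coords)[2])
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(traj$coords)[1])) {
    fr <- get_frame(traj, i)
    writeLines(c(as.character(nrow(fr)), paste("frame", i)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}
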