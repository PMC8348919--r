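#' van der Waals parameters used by the steric probe field
#'
#' Element-keyed 6-12 potential parameters (minimum-energy radius R in
#' Angstrom, well depth eps in kcal/mol) in the style of the Tripos force
#' field tables; combined probe-atom parameters are `R_i + R_probe` and
#' `sqrt(eps_i * eps_probe)`.
#'
#' @param element character vector of element symbols.
#' @return data.frame with columns `element`, `r_vdw`, `eps`.
#' @export
vdw_params <- function(element) {
  tab <- data.frame(
    element = c("H",   "C",   "N",    "O",    "F",    "S",   "Cl",  "Br",  "I",    "P"),
    r_vdw   = c(1.50,  1.70,  1.55,   1.52,   1.47,   1.80,  1.75,  1.85,  1.98,   1.80),
    eps     = c(0.042, 0.107, 0.095,  0.116,  0.109,  0.314, 0.314, 0.434, 0.623,  0.314),
    stringsAsFactors = FALSE)
  idx <- match(element, tab$element)
  if (anyNA(idx)) {
    stop("no vdW parameters for element(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

#' The default lattice probe: an sp3 carbon with +1 e charge
#' @return list with `element`, `charge`, `r_vdw`, `eps`.
#' @export
comfa_probe <- function() {
  p <- vdw_params("C")
  list(element = "C", charge = 1.0, r_vdw = p$r_vdw, eps = p$eps)
}

#' Build a shared rectangular lattice around a set of aligned conformers
#'
#' The box is the union bounding box of all atoms expanded by `margin` on
#' every side, discretized at `spacing`; grid lines start at the expanded
#' minimum and extend until the expanded maximum is covered.
#'
#' @param conformers a conformer or list of conformers.
#' @param spacing grid step in Angstrom (> 0).
#' @param margin padding in Angstrom added on all sides.
#' @return object of class `lattice`: list(origin, spacing, dims).
#' @export
build_lattice <- function(conformers, spacing = 2.0, margin = 4.0) {
  stopifnot(spacing > 0, margin >= 0)
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (!length(conformers)) stop("need at least one conformer")
  xyz <- do.call(rbind, lapply(conformers, conformer_xyz))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  structure(list(origin = as.numeric(lo), spacing = spacing, dims = dims),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("<lattice %dx%dx%d, spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid point coordinates of a lattice
#'
#' @param lattice a [build_lattice()] object.
#' @return n x 3 matrix; x varies fastest, then y, then z.
#' @export
lattice_points <- function(lattice) {
  ax <- lapply(1:3, function(k) {
    lattice$origin[k] + (seq_len(lattice$dims[k]) - 1) * lattice$spacing
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' @keywords internal
point_atom_dist2 <- function(points, xyz) {
  # n_points x n_atoms squared distances
  p2 <- rowSums(points^2)
  a2 <- rowSums(xyz^2)
  d2 <- outer(p2, a2, "+") - 2 * points %*% t(xyz)
  pmax(d2, 0)
}

#' Steric (Lennard-Jones) probe field on a lattice
#'
#' At each grid point the 6-12 interaction energy of the probe with every
#' atom is summed: `eps_ij * ((R_ij/r)^12 - 2 (R_ij/r)^6)` with combined
#' parameters `R_ij = r_i + r_probe`, `eps_ij = sqrt(eps_i eps_probe)`.
#' Values are truncated to `[-cap, +cap]`; the positive cap marks steric
#' clash regions (see attribute `clash`).
#'
#' @param conf a conformer.
#' @param lattice shared lattice.
#' @param probe probe parameters, see [comfa_probe()].
#' @param cap truncation bound in kcal/mol.
#' @return numeric vector over grid points (kcal/mol) with logical
#'   attribute `clash` flagging capped points.
#' @export
steric_field <- function(conf, lattice, probe = comfa_probe(), cap = 30) {
  xyz <- conformer_xyz(conf)
  par <- vdw_params(conf$atoms$element)
  pts <- lattice_points(lattice)
  d2 <- point_atom_dist2(pts, xyz)
  Rij <- par$r_vdw + probe$r_vdw
  epsij <- sqrt(par$eps * probe$eps)
  # (R^2/r^2)^3 per point-atom pair, scaled per atom
  s6 <- sweep(1 / pmax(d2, 1e-12), 2, Rij^2, "*")^3
  e <- s6 * (s6 - 2)
  v <- as.vector(e %*% epsij)
  clash <- v >= cap
  v <- pmin(pmax(v, -cap), cap)
  attr(v, "clash") <- clash
  v
}

#' Electrostatic (Coulomb) probe field with distance-dependent dielectric
#'
#' Coulomb sum `332.06 * q_probe * q_atom / r^2` (kcal/mol; the 1/r^2 form
#' is the 1/(eps r) potential with eps = r). Returns raw sums; masking of
#' steric-clash points by their column mean happens at matrix assembly
#' ([comfa_matrix()]), where the across-compound mean is defined.
#'
#' @param conf a conformer with partial charges.
#' @param lattice shared lattice.
#' @param probe_charge probe charge in e.
#' @return numeric vector over grid points (kcal/mol).
#' @export
electrostatic_field <- function(conf, lattice, probe_charge = 1.0) {
  xyz <- conformer_xyz(conf)
  q <- conf$atoms$charge
  pts <- lattice_points(lattice)
  d2 <- point_atom_dist2(pts, xyz)
  as.vector((332.06 * probe_charge / pmax(d2, 1e-12)) %*% q)
}

#' @keywords internal
comsia_weights <- function(conf, field) {
  at <- conf$atoms
  switch(field,
    S = vdw_params(at$element)$r_vdw^3,
    E = at$charge,
    H = if (!is.null(at$logp)) at$logp else
      stop("conformer lacks per-atom hydrophobicity ('logp') for field H"),
    D = if (!is.null(at$donor)) as.numeric(at$donor) else
      stop("conformer lacks donor flags for field D"),
    A = if (!is.null(at$acceptor)) as.numeric(at$acceptor) else
      stop("conformer lacks acceptor flags for field A"),
    stop("unknown similarity field type: ", field))
}

#' Gaussian similarity-index fields (CoMSIA style)
#'
#' The similarity index at grid point k for property p is
#' `-sum_i w_probe * w_i * exp(-alpha * r_ik^2)`; Gaussian attenuation
#' makes the field bounded everywhere, including at atom centers.
#' Property weights: S = vdW radius cubed, E = partial charge,
#' H = Crippen atomic logP contribution, D/A = donor/acceptor indicator;
#' the probe weight is +1 for every field.
#'
#' @param conf annotated conformer.
#' @param lattice shared lattice.
#' @param alpha attenuation factor in 1/Angstrom^2.
#' @param fields subset of c("S","E","H","D","A").
#' @return matrix n_gridpoints x length(fields), column names = fields.
#' @export
similarity_fields <- function(conf, lattice, alpha = 0.3,
                              fields = c("S", "E", "H", "D", "A")) {
  stopifnot(alpha > 0)
  fields <- match.arg(fields, c("S", "E", "H", "D", "A"), several.ok = TRUE)
  pts <- lattice_points(lattice)
  G <- exp(-alpha * point_atom_dist2(pts, conformer_xyz(conf)))
  out <- matrix(0, nrow(pts), length(fields),
                dimnames = list(NULL, fields))
  for (f in fields) out[, f] <- -as.vector(G %*% comsia_weights(conf, f))
  out
}

#' @keywords internal
new_field_matrix <- function(values, lattice, column_meta, dropped_meta = NULL) {
  stopifnot(ncol(values) == nrow(column_meta))
  if (any(!is.finite(values))) stop("field matrix contains non-finite values")
  structure(list(values = values, lattice = lattice, column_meta = column_meta,
                 dropped_meta = dropped_meta %||%
                   column_meta[0, , drop = FALSE]),
            class = "field_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.field_matrix <- function(x, ...) {
  cat(sprintf("<field_matrix %d compounds x %d columns (%s)%s>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$column_meta$field), collapse = ","),
              if (nrow(x$dropped_meta)) sprintf(", %d dropped",
                                                nrow(x$dropped_meta)) else ""))
  invisible(x)
}

#' Assemble the CoMFA-style descriptor matrix (steric + electrostatic)
#'
#' One row per aligned conformer; the steric block is followed by the
#' electrostatic block. Electrostatic values at grid points inside a
#' compound's steric clash region are replaced by that column's mean over
#' the non-clashed compounds (0 when every compound clashes there).
#'
#' @param conformers list of aligned conformers.
#' @param lattice shared lattice (defaults to [build_lattice()] of the set).
#' @param probe probe parameters.
#' @param cap steric truncation, kcal/mol.
#' @return a `field_matrix`; `column_meta` has `grid_index` and `field`
#'   ("S_lj", "E_coul").
#' @export
comfa_matrix <- function(conformers, lattice = NULL, probe = comfa_probe(),
                         cap = 30) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  lattice <- lattice %||% build_lattice(conformers)
  n <- length(conformers)
  npts <- prod(lattice$dims)
  S <- matrix(0, n, npts); E <- matrix(0, n, npts); clash <- matrix(FALSE, n, npts)
  for (i in seq_len(n)) {
    sv <- steric_field(conformers[[i]], lattice, probe, cap)
    S[i, ] <- sv
    clash[i, ] <- attr(sv, "clash")
    E[i, ] <- electrostatic_field(conformers[[i]], lattice, probe$charge)
  }
  for (j in which(colSums(clash) > 0)) {
    ok <- !clash[, j]
    E[!ok, j] <- if (any(ok)) mean(E[ok, j]) else 0
  }
  meta <- data.frame(grid_index = rep(seq_len(npts), 2),
                     field = rep(c("S_lj", "E_coul"), each = npts),
                     stringsAsFactors = FALSE)
  new_field_matrix(cbind(S, E), lattice, meta)
}

#' Assemble the CoMSIA-style descriptor matrix
#'
#' @param conformers list of aligned, property-annotated conformers.
#' @param lattice shared lattice (defaults to [build_lattice()] of the set).
#' @param alpha Gaussian attenuation, 1/Angstrom^2.
#' @param fields similarity field menu, subset of c("S","E","H","D","A").
#' @return a `field_matrix` with one column block per field type.
#' @export
comsia_matrix <- function(conformers, lattice = NULL, alpha = 0.3,
                          fields = c("S", "E", "H", "D", "A")) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  lattice <- lattice %||% build_lattice(conformers)
  npts <- prod(lattice$dims)
  vals <- t(vapply(conformers, function(cf) {
    as.vector(similarity_fields(cf, lattice, alpha, fields))
  }, numeric(npts * length(fields))))
  if (length(conformers) == 1) vals <- matrix(vals, nrow = 1)
  meta <- data.frame(grid_index = rep(seq_len(npts), length(fields)),
                     field = rep(fields, each = npts),
                     stringsAsFactors = FALSE)
  new_field_matrix(vals, lattice, meta)
}

#' Drop near-constant descriptor columns
#'
#' Removes columns whose standard deviation across compounds is below
#' `min_sigma`, recording them in `dropped_meta`. Applying the filter
#' twice equals applying it once.
#'
#' @param fm a `field_matrix`.
#' @param min_sigma minimum column standard deviation to keep.
#' @return the filtered `field_matrix`.
#' @export
filter_columns <- function(fm, min_sigma) {
  stopifnot(inherits(fm, "field_matrix"), min_sigma >= 0)
  sds <- apply(fm$values, 2, stats::sd)
  keep <- sds >= min_sigma | (min_sigma == 0)
  new_field_matrix(fm$values[, keep, drop = FALSE], fm$lattice,
                   fm$column_meta[keep, , drop = FALSE],
                   rbind(fm$dropped_meta, fm$column_meta[!keep, , drop = FALSE]))
}

#' Export one lattice scalar field in OpenDX grid format
#'
#' @param values numeric vector over the lattice (x fastest ordering, as
#'   produced by the field functions).
#' @param lattice the lattice.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(values, lattice, path) {
  stopifnot(length(values) == prod(lattice$dims))
  d <- lattice$dims
  # OpenDX expects z-fastest ordering; internal storage is x-fastest
  v <- as.vector(aperm(array(values, dim = d), c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f",
                     lattice$origin[1], lattice$origin[2], lattice$origin[3]), con)
  writeLines(c(sprintf("delta %.6f 0 0", lattice$spacing),
               sprintf("delta 0 %.6f 0", lattice$spacing),
               sprintf("delta 0 0 %.6f", lattice$spacing),
               sprintf("object 2 class gridconnections counts %d %d %d",
                       d[1], d[2], d[3]),
               sprintf("object 3 class array type double rank 0 items %d data follows",
                       length(v))), con)
  idx <- seq(1, length(v), by = 3)
  lines <- vapply(idx, function(i) {
    paste(sprintf("%.6e", v[i:min(i + 2, length(v))]), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
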