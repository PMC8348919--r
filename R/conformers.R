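#' @keywords internal
rdkit_helper <- function() {
  path <- system.file("python", "rdkit_helper.py", package = "xoiqsar")
  if (!nzchar(path)) stop("bundled rdkit helper not found")
  path
}

#' @keywords internal
rdkit_call <- function(args) {
  python <- Sys.which("python")
  if (!nzchar(python)) stop("python interpreter not found on PATH")
  out <- suppressWarnings(system2(python, c(shQuote(rdkit_helper()), shQuote(args)),
                                  stdout = TRUE, stderr = FALSE))
  res <- tryCatch(jsonlite::fromJSON(paste(out, collapse = ""),
                                     simplifyDataFrame = TRUE),
                  error = function(e) stop("rdkit helper produced no parsable output"))
  if (!is.null(res$error)) stop("rdkit helper: ", res$error)
  res
}

#' Construct a conformer object from raw atom data
#'
#' A conformer is a molecule with one set of 3D coordinates (Angstrom),
#' per-atom partial charges and (optionally) the property annotations the
#' field engine and pharmacophore typing use.
#'
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`;
#'   optionally `charge` (e), `logp` (Crippen atomic hydrophobicity),
#'   `donor`, `acceptor` (logical), `formal` (formal charge), `aromatic`.
#' @param compound_id identifier carried through the pipeline.
#' @param smiles originating structure string, if any.
#' @param rings list of integer atom-index vectors (ring membership).
#' @param bonds optional 3-column matrix (atom1, atom2, order).
#' @return object of class `conformer`.
#' @export
conformer <- function(atoms, compound_id = NA_character_, smiles = NA_character_,
                      rings = list(), bonds = NULL) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))) ||
      any(!is.finite(atoms$charge))) {
    stop("conformer coordinates and charges must be finite")
  }
  structure(list(compound_id = compound_id, smiles = smiles, atoms = atoms,
                 rings = rings, bonds = bonds, core_idx = integer(0),
                 core_rmsd = NA_real_),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s: %d atoms%s>\n", x$compound_id, nrow(x$atoms),
              if (is.finite(x$core_rmsd))
                sprintf(", core rmsd %.4f A", x$core_rmsd) else ""))
  invisible(x)
}

#' Coordinate matrix of a conformer
#' @param conf a `conformer`.
#' @return numeric matrix n_atoms x 3 (Angstrom).
#' @export
conformer_xyz <- function(conf) {
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

#' Embed a single low-energy 3D conformer from SMILES
#'
#' Generates one 3D conformer with a seeded distance-geometry embedding
#' followed by force-field minimization, and assigns Gasteiger partial
#' charges, Crippen atomic hydrophobicity contributions, and rule-based
#' hydrogen-bond donor/acceptor flags. The same (smiles, seed) pair always
#' yields bitwise-identical output.
#'
#' @param smiles structure string.
#' @param seed integer random seed for the embedding.
#' @param compound_id identifier to attach.
#' @return a [conformer()] with hydrogens explicit.
#' @export
embed_conformer <- function(smiles, seed = 1L, compound_id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  res <- rdkit_call(c("embed", smiles, as.integer(seed)))
  atoms <- as.data.frame(res$atoms)
  rings <- if (length(res$rings)) lapply(res$rings, as.integer) else list()
  bonds <- if (length(res$bonds)) matrix(as.integer(res$bonds), ncol = 3) else NULL
  conformer(atoms, compound_id = compound_id, smiles = smiles, rings = rings,
            bonds = bonds)
}

#' Substructure match atom indices
#'
#' @param smiles molecule SMILES (atom indexing: heavy atoms first, in
#'   input order, as produced by [embed_conformer()]).
#' @param smarts SMARTS query.
#' @return list of integer vectors, one per match, query-atom order.
#' @export
substructure_matches <- function(smiles, smarts) {
  res <- rdkit_call(c("match", smiles, smarts))
  m <- res$matches
  if (is.matrix(m)) m <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  lapply(m, as.integer)
}

#' Kabsch superposition of two point sets
#'
#' Least-squares optimal rigid-body superposition (proper rotation only;
#' the reflection case is corrected by flipping the smallest singular
#' direction) of `moving` onto `fixed`.
#'
#' @param moving,fixed n x 3 coordinate matrices, row-correspondent.
#' @return list with `rotation` (3x3), `translation` (length 3; the
#'   transform is `sweep(moving, 2, cm) %*% rotation + cf`), `rmsd`, and
#'   `transform(xyz)` applying the fitted motion to arbitrary points.
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(ncol(moving) == 3, ncol(fixed) == 3, nrow(moving) == nrow(fixed),
            nrow(moving) >= 1)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  aligned <- P %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  transform <- function(xyz) {
    sweep(sweep(as.matrix(xyz), 2, cm) %*% R, 2, cf, "+")
  }
  list(rotation = R, translation = cf - as.vector(cm %*% R), rmsd = rmsd,
       transform = transform)
}

#' Align a conformer onto a template's common core
#'
#' Matches `core_pattern` (SMARTS) in both molecules, then applies the
#' rigid-body (Kabsch) transform that minimizes the least-squares deviation
#' of the matched core atoms, moving all atoms with the core. When several
#' substructure matches exist on either side, the pairing with the smallest
#' core RMSD wins; exact ties go to the lexicographically smallest atom
#' index combination (match enumeration order).
#'
#' @param conf conformer to move.
#' @param template reference conformer (unchanged).
#' @param core_pattern SMARTS for the shared core. Alternatively pass
#'   explicit index pairings via `conf_idx`/`template_idx`.
#' @param conf_idx,template_idx optional equal-length integer vectors of
#'   row-correspondent core atom indices, bypassing SMARTS matching.
#' @return the moved conformer with `core_idx` and `core_rmsd` set.
#' @export
align_to_core <- function(conf, template, core_pattern = NULL,
                          conf_idx = NULL, template_idx = NULL) {
  stopifnot(inherits(conf, "conformer"), inherits(template, "conformer"))
  if (is.null(conf_idx) || is.null(template_idx)) {
    if (is.null(core_pattern)) stop("need core_pattern or explicit index maps")
    cm <- substructure_matches(conf$smiles, core_pattern)
    tm <- substructure_matches(template$smiles, core_pattern)
    if (!length(cm) || !length(tm)) {
      stop("core pattern does not match both molecules: ", core_pattern)
    }
    best <- NULL
    for (ti in tm) for (ci in cm) {
      fit <- kabsch(conformer_xyz(conf)[ci, , drop = FALSE],
                    conformer_xyz(template)[ti, , drop = FALSE])
      if (is.null(best) || fit$rmsd < best$rmsd - 1e-12) {
        best <- list(rmsd = fit$rmsd, ci = ci, ti = ti, fit = fit)
      }
    }
    conf_idx <- best$ci; template_idx <- best$ti; fit <- best$fit
  } else {
    stopifnot(length(conf_idx) == length(template_idx))
    fit <- kabsch(conformer_xyz(conf)[conf_idx, , drop = FALSE],
                  conformer_xyz(template)[template_idx, , drop = FALSE])
  }
  moved <- conf
  moved$atoms[, c("x", "y", "z")] <- fit$transform(conformer_xyz(conf))
  moved$core_idx <- as.integer(conf_idx)
  moved$core_rmsd <- fit$rmsd
  moved
}

#' Write conformers to an SDF (V2000) file
#'
#' Minimal V2000 writer for aligned conformer sets; coordinates in
#' Angstrom, no charge block (partial charges are not part of V2000).
#'
#' @param confs a conformer or list of conformers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conformer_sdf <- function(confs, path) {
  if (inherits(confs, "conformer")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in confs) {
    at <- cf$atoms
    nb <- if (is.null(cf$bonds)) 0L else nrow(cf$bonds)
    writeLines(c(as.character(cf$compound_id), "  xoiqsar 3D", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nb), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z, at$element), con)
    if (nb > 0) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", cf$bonds[, 1], cf$bonds[, 2],
                         cf$bonds[, 3]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
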