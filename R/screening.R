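#' Construct a pharmacophore hypothesis
#'
#' A hypothesis is a set of typed feature spheres: hydrogen-bond acceptor
#' (HA) and donor (HD) atoms, hydrophobic centers (HY) and negative
#' centers (NC), each with a center and a tolerance radius.
#'
#' @param kind character vector in {"HA","HD","HY","NC"}.
#' @param x,y,z feature centers (Angstrom).
#' @param radius tolerance radii (Angstrom, > 0), recycled.
#' @return data.frame of class `pharmacophore`.
#' @export
pharmacophore <- function(kind, x, y, z, radius = 1.0) {
  stopifnot(length(kind) >= 1, all(kind %in% c("HA", "HD", "HY", "NC")))
  out <- data.frame(kind = kind, x = x, y = y, z = z,
                    radius = rep_len(radius, length(kind)),
                    stringsAsFactors = FALSE)
  if (any(out$radius <= 0)) stop("feature radii must be positive")
  class(out) <- c("pharmacophore", "data.frame")
  out
}

#' Read / write a pharmacophore hypothesis as JSON
#' @param path file path.
#' @return [read_pharmacophore()] returns a [pharmacophore()].
#' @export
read_pharmacophore <- function(path) {
  d <- jsonlite::fromJSON(path)
  f <- d$features
  pharmacophore(f$kind, f$x, f$y, f$z, f$radius)
}

#' @rdname read_pharmacophore
#' @param hypothesis a [pharmacophore()].
#' @export
write_pharmacophore <- function(hypothesis, path) {
  jsonlite::write_json(list(features = as.data.frame(hypothesis)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Typed pharmacophore feature points of a conformer
#'
#' Rule-based typing from the conformer's atom annotations: HD = donor
#' atoms, HA = acceptor atoms, HY = centroids of all-carbon rings,
#' NC = formally negative atoms plus carboxyl(ate) group centroids when
#' the conformer's structure string is available for matching.
#'
#' @param conf an annotated [conformer()] (from [embed_conformer()]).
#' @return data.frame with `kind`, `x`, `y`, `z`.
#' @export
conformer_features <- function(conf) {
  at <- conf$atoms
  feats <- list()
  add <- function(kind, xyz) {
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    if (nrow(xyz)) data.frame(kind = kind, x = xyz[, 1], y = xyz[, 2],
                              z = xyz[, 3], stringsAsFactors = FALSE)
  }
  xyz <- conformer_xyz(conf)
  if (!is.null(at$donor)) feats$hd <- add("HD", xyz[which(at$donor), , drop = FALSE])
  if (!is.null(at$acceptor)) feats$ha <- add("HA", xyz[which(at$acceptor), , drop = FALSE])
  if (length(conf$rings)) {
    carbo <- Filter(function(r) all(at$element[r] == "C"), conf$rings)
    if (length(carbo)) {
      cent <- t(vapply(carbo, function(r) colMeans(xyz[r, , drop = FALSE]),
                       numeric(3)))
      feats$hy <- add("HY", cent)
    }
  }
  neg <- which((at$formal %||% rep(0, nrow(at))) < 0)
  nc_pts <- xyz[neg, , drop = FALSE]
  if (!is.na(conf$smiles)) {
    cx <- tryCatch(
      substructure_matches(conf$smiles, "[CX3](=O)[OX2H1,OX1-]"),
      error = function(e) list())
    if (length(cx)) {
      cent <- t(vapply(cx, function(idx) colMeans(xyz[idx, , drop = FALSE]),
                       numeric(3)))
      nc_pts <- rbind(nc_pts, cent)
    }
  }
  feats$nc <- add("NC", nc_pts)
  out <- do.call(rbind, feats)
  if (is.null(out)) out <- data.frame(kind = character(0), x = numeric(0),
                                      y = numeric(0), z = numeric(0))
  rownames(out) <- NULL
  out
}

#' Score a molecule against a pharmacophore hypothesis (QFIT surrogate)
#'
#' Greedy one-to-one assignment: hypothesis features are visited in row
#' order and each takes the nearest unassigned molecule feature point of
#' the same kind within its radius. The score is
#' `100 * (matched/total) * exp(-msd / mean(radius^2))` where msd is the
#' mean squared center deviation over matched pairs; 0 when nothing
#' matches. This declared surrogate scores feature-sphere compliance on
#' the 0-100 scale; it makes no claim of equivalence to any proprietary
#' fitness function.
#'
#' @param conf a [conformer()] or a feature data.frame (see
#'   [conformer_features()]).
#' @param hypothesis a [pharmacophore()].
#' @return list with `qfit` in [0, 100], `matched_features`,
#'   `total_features`, and the per-feature `assignment` data.frame.
#' @export
match_qfit <- function(conf, hypothesis) {
  stopifnot(inherits(hypothesis, "pharmacophore"))
  feats <- if (inherits(conf, "conformer")) conformer_features(conf) else conf
  total <- nrow(hypothesis)
  used <- rep(FALSE, nrow(feats))
  dev2 <- numeric(0)
  hit <- logical(total)
  for (i in seq_len(total)) {
    cand <- which(!used & feats$kind == hypothesis$kind[i])
    if (!length(cand)) next
    d2 <- (feats$x[cand] - hypothesis$x[i])^2 +
      (feats$y[cand] - hypothesis$y[i])^2 +
      (feats$z[cand] - hypothesis$z[i])^2
    j <- cand[which.min(d2)]
    if (min(d2) <= hypothesis$radius[i]^2) {
      used[j] <- TRUE
      hit[i] <- TRUE
      dev2 <- c(dev2, min(d2))
    }
  }
  m <- sum(hit)
  qfit <- if (m == 0) 0 else
    100 * (m / total) * exp(-mean(dev2) / mean(hypothesis$radius^2))
  list(qfit = qfit, matched_features = m, total_features = total,
       assignment = data.frame(kind = hypothesis$kind, matched = hit))
}

#' Enrichment factor and Guner-Henry score of a hit list
#'
#' For a screen of a database of `D` compounds containing `A` actives that
#' returns `Ht` hits of which `Ha` are active:
#' `EF = (Ha/Ht) / (A/D)` and
#' `GH = (Ha*(3A + Ht) / (4*Ht*A)) * (1 - (Ht - Ha)/(D - A))`.
#' An empty hit list gives both scores 0 with a warning.
#'
#' @param Ha true positives in the hit list.
#' @param Ht hit-list size.
#' @param A actives in the database.
#' @param D database size.
#' @return list with `Ha`, `Ht`, `A`, `D`, `ef`, `gh`.
#' @export
enrichment <- function(Ha, Ht, A, D) {
  v <- c(Ha = Ha, Ht = Ht, A = A, D = D)
  if (any(v != round(v)) || any(v < 0)) stop("counts must be non-negative integers")
  Ha <- as.integer(Ha); Ht <- as.integer(Ht)
  A <- as.integer(A); D <- as.integer(D)
  if (!(Ha <= Ht && Ht <= D && Ha <= A && A <= D && (Ht - Ha) <= (D - A))) {
    stop("count invariants violated: need Ha <= Ht <= D, Ha <= A <= D, ",
         "and Ht - Ha <= D - A (false positives cannot exceed decoys)")
  }
  if (Ht == 0) {
    warning("empty hit list; EF and GH set to 0")
    return(list(Ha = Ha, Ht = Ht, A = A, D = D, ef = 0, gh = 0))
  }
  ef <- (Ha / Ht) / (A / D)
  gh <- (Ha * (3 * A + Ht) / (4 * Ht * A)) * (1 - (Ht - Ha) / (D - A))
  list(Ha = Ha, Ht = Ht, A = A, D = D, ef = ef, gh = gh)
}

#' Physicochemical descriptors for the ADME table
#'
#' MW, topological polar surface area, logP and hydrogen-bond counts come
#' from Open Babel's descriptor engine; rotatable bonds (non-ring single
#' bonds between non-terminal heavy atoms, triple-bond-adjacent excluded)
#' and sp3 carbon fraction are SMARTS counts.
#'
#' @param smiles character vector of structure strings.
#' @return data.frame with `smiles`, `mw` (g/mol), `tpsa` (Angstrom^2),
#'   `logp`, `hbd`, `hba`, `rotatable_bonds`, `fraction_csp3`.
#' @export
basic_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  props <- ChemmineOB::prop_OB(mols)
  rot <- ChemmineOB::smartsSearch_OB(mols, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  csp3 <- ChemmineOB::smartsSearch_OB(mols, "[CX4]")
  allc <- ChemmineOB::smartsSearch_OB(mols, "[#6]")
  data.frame(smiles = smiles, mw = props$MW, tpsa = props$TPSA,
             logp = props$logP, hbd = props$HBD, hba = props$HBA1,
             rotatable_bonds = as.integer(rot),
             fraction_csp3 = ifelse(allc > 0, csp3 / allc, 0),
             stringsAsFactors = FALSE)
}

#' Count violations of Lipinski's rule of five
#'
#' One violation per breached bound: MW > 500 g/mol, logP > 5,
#' H-bond donors > 5, H-bond acceptors (N+O count) > 10.
#'
#' @param x SMILES character vector or a [basic_descriptors()] data.frame.
#' @return integer vector of violation counts.
#' @export
lipinski_violations <- function(x) {
  d <- if (is.character(x)) basic_descriptors(x) else x
  as.integer((d$mw > 500) + (d$logp > 5) + (d$hbd > 5) + (d$hba > 10))
}

#' Configuration of the staged virtual-screening funnel
#'
#' Stage 1 keeps candidates with pharmacophore score `qfit > qfit_min`;
#' stage 2 keeps `docking_score > dock_min`; stage 3 applies the ADME
#' gate: mw_range < MW < (exclusive), TPSA within tpsa_range, GI
#' absorption "High", no blood-brain-barrier permeation, synthetic
#' accessibility < sa_max, Lipinski violations == 0, and at most cyp_max
#' of the five CYP450 inhibition flags.
#'
#' Numeric bounds are compared with a half-unit-of-printed-precision
#' tolerance by default (`precision_tol = TRUE`): a bound written "130"
#' admits values under 130.5, "4.5" admits under 4.55. This is the only
#' reading under which the reference hit table that motivated these gates
#' is self-consistent (one of its hits carries TPSA 130.3). Set
#' `precision_tol = FALSE` for strict printed inequalities.
#'
#' @param qfit_min stage-1 pharmacophore score threshold.
#' @param dock_min stage-2 docking score threshold.
#' @param mw_range,tpsa_range exclusive (lo, hi) windows.
#' @param sa_max synthetic accessibility bound.
#' @param cyp_max maximum CYP450 inhibition flags allowed.
#' @param precision_tol compare bounds at their printed precision.
#' @return list of class `funnel_config`.
#' @export
funnel_config <- function(qfit_min = 35, dock_min = 10,
                          mw_range = c(150, 500), tpsa_range = c(20, 130),
                          sa_max = 4.5, cyp_max = 1, precision_tol = TRUE) {
  structure(list(qfit_min = qfit_min, dock_min = dock_min,
                 mw_range = mw_range, tpsa_range = tpsa_range,
                 sa_max = sa_max, cyp_max = cyp_max,
                 precision_tol = precision_tol),
            class = "funnel_config")
}

#' @keywords internal
bound_tol <- function(bound, enabled) {
  if (!enabled) return(0)
  dec <- nchar(sub("^[^.]*\\.?", "", sub("0+$", "", format(bound, scientific = FALSE))))
  0.5 * 10^(-dec)
}

#' ADME gate predicate
#'
#' @param candidates data.frame with columns `mw`, `tpsa`, `gi_absorption`
#'   ("High"/"Low"), `bbb_permeant` (logical or "Yes"/"No"), `sa_score`,
#'   `lipinski_violations`, and the five CYP flags `cyp1a2`, `cyp2c19`,
#'   `cyp2c9`, `cyp2d6`, `cyp3a4` (logical or "Yes"/"No").
#' @param config a [funnel_config()].
#' @return logical vector, one per row.
#' @export
adme_gate <- function(candidates, config = funnel_config()) {
  need <- c("mw", "tpsa", "gi_absorption", "bbb_permeant", "sa_score",
            "lipinski_violations", "cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6",
            "cyp3a4")
  missing <- setdiff(need, names(candidates))
  if (length(missing)) stop("ADME gate missing column(s): ",
                            paste(missing, collapse = ", "))
  yes <- function(v) if (is.logical(v)) v else tolower(v) %in% c("yes", "true")
  tolmw <- bound_tol(config$mw_range[2], config$precision_tol)
  toltp <- bound_tol(config$tpsa_range[2], config$precision_tol)
  tolsa <- bound_tol(config$sa_max, config$precision_tol)
  cyp <- yes(candidates$cyp1a2) + yes(candidates$cyp2c19) +
    yes(candidates$cyp2c9) + yes(candidates$cyp2d6) + yes(candidates$cyp3a4)
  candidates$mw > config$mw_range[1] - tolmw &
    candidates$mw < config$mw_range[2] + tolmw &
    candidates$tpsa > config$tpsa_range[1] - toltp &
    candidates$tpsa < config$tpsa_range[2] + toltp &
    tolower(candidates$gi_absorption) == "high" &
    !yes(candidates$bbb_permeant) &
    candidates$sa_score < config$sa_max + tolsa &
    candidates$lipinski_violations == 0 &
    cyp <= config$cyp_max
}

#' Run the staged virtual-screening funnel
#'
#' Stages are applied in order (pharmacophore score, docking score, ADME
#' gate); each stage's survivors feed the next. Rows missing a value
#' required by a stage are rejected at that stage with a reason. Survivors
#' are always a subset of the input and independent of row order.
#'
#' @param candidates data.frame with `compound_id`, `qfit`,
#'   `docking_score`, and the [adme_gate()] columns.
#' @param config a [funnel_config()].
#' @return list of class `funnel_result`: `stages` (named list of
#'   surviving data.frames), `counts`, `rejected` (with `stage`, `reason`).
#' @export
run_funnel <- function(candidates, config = funnel_config()) {
  stopifnot(is.data.frame(candidates))
  if (!"compound_id" %in% names(candidates)) {
    stop("candidates need a compound_id column")
  }
  rejected <- data.frame(compound_id = character(0), stage = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  reject <- function(ids, stage, reason) {
    if (length(ids)) rbind(rejected, data.frame(compound_id = ids,
                                                stage = stage, reason = reason,
                                                stringsAsFactors = FALSE))
    else rejected
  }
  cur <- candidates

  stage_filter <- function(cur, col, min, stage) {
    if (!col %in% names(cur)) {
      rejected <<- reject(cur$compound_id, stage, paste0("missing column ", col))
      return(cur[0, , drop = FALSE])
    }
    na <- !is.finite(cur[[col]])
    rejected <<- reject(cur$compound_id[na], stage, paste0("missing ", col))
    cur <- cur[!na, , drop = FALSE]
    fail <- !(cur[[col]] > min)
    rejected <<- reject(cur$compound_id[fail], stage,
                        sprintf("%s <= %s", col, format(min)))
    cur[!fail, , drop = FALSE]
  }

  s1 <- stage_filter(cur, "qfit", config$qfit_min, "pharmacophore")
  s2 <- stage_filter(s1, "docking_score", config$dock_min, "docking")
  need <- c("mw", "tpsa", "gi_absorption", "bbb_permeant", "sa_score",
            "lipinski_violations", "cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6",
            "cyp3a4")
  missing_cols <- setdiff(need, names(s2))
  if (length(missing_cols) && nrow(s2)) {
    rejected <- reject(s2$compound_id, "adme",
                       paste("missing column(s):",
                             paste(missing_cols, collapse = ", ")))
    s3 <- s2[0, , drop = FALSE]
  } else if (nrow(s2)) {
    complete <- stats::complete.cases(s2[, need])
    rejected <- reject(s2$compound_id[!complete], "adme", "missing ADME value")
    s2c <- s2[complete, , drop = FALSE]
    pass <- adme_gate(s2c, config)
    rejected <- reject(s2c$compound_id[!pass], "adme", "failed ADME gate")
    s3 <- s2c[pass, , drop = FALSE]
  } else {
    s3 <- s2
  }
  structure(list(stages = list(pharmacophore = s1, docking = s2, adme = s3),
                 counts = c(input = nrow(candidates), pharmacophore = nrow(s1),
                            docking = nrow(s2), adme = nrow(s3)),
                 rejected = rejected, config = config),
            class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("<funnel_result: ", paste(names(x$counts), x$counts, sep = " = ",
                                collapse = ", "), ">\n", sep = "")
  invisible(x)
}
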