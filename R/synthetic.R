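#' Synthetic field-descriptor dataset with a planted linear activity
#'
#' Emulates the statistical structure of a lattice-field QSAR problem:
#' the descriptor matrix comes from a low-rank latent factor model (plus a
#' small full-rank perturbation so columns are not exactly collinear), and
#' the activity is a linear function of the descriptors with planted
#' coefficients lying in the span of the factor loadings (so a
#' latent-variable regression can recover them) plus homoscedastic
#' Gaussian noise. All output is a pure function of the arguments.
#'
#' @param n_samples compounds (rows).
#' @param n_cols descriptor columns.
#' @param n_latent latent factors generating X.
#' @param coefficient_scale scale of the planted coefficient vector.
#' @param noise_sigma activity noise standard deviation (activity units).
#' @param x_noise small full-rank descriptor perturbation.
#' @param seed integer seed.
#' @return list with `X` (n x p), `y`, `coefficients` (planted b),
#'   `n_latent`, `seed`.
#' @export
make_field_dataset <- function(n_samples = 40, n_cols = 50, n_latent = 3,
                               coefficient_scale = 1, noise_sigma = 0.1,
                               x_noise = 0.01, seed = 1L) {
  stopifnot(n_samples > 0, n_cols > 0, n_latent > 0, noise_sigma >= 0)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  Tm <- matrix(stats::rnorm(n_samples * n_latent), n_samples, n_latent)
  P <- matrix(stats::rnorm(n_cols * n_latent), n_cols, n_latent)
  X <- Tm %*% t(P) + x_noise * matrix(stats::rnorm(n_samples * n_cols),
                                      n_samples, n_cols)
  g <- stats::rnorm(n_latent)
  b <- as.vector(P %*% g)
  b <- coefficient_scale * b / sqrt(sum(b^2))
  y <- as.vector(X %*% b) + stats::rnorm(n_samples, sd = noise_sigma)
  list(X = X, y = y, coefficients = b, n_latent = n_latent, seed = seed)
}

#' Synthetic active/decoy screening outcome
#'
#' Labels `A` actives and `D - A` decoys, then draws each compound's
#' hit-list membership as an independent Bernoulli with the stated
#' retrieval rates (expected Ha = A * true_rate).
#'
#' @param A actives in the database.
#' @param D database size (actives + decoys).
#' @param true_rate retrieval probability for actives.
#' @param false_rate retrieval probability for decoys.
#' @param seed integer seed.
#' @return data.frame with `id`, `active`, `hit`, plus attribute
#'   `enrichment` (the [enrichment()] of the realized counts).
#' @export
make_decoy_screen <- function(A = 35, D = 6269, true_rate = 1.0,
                              false_rate = 0.0027, seed = 1L) {
  stopifnot(A >= 0, D >= A, true_rate >= 0, true_rate <= 1,
            false_rate >= 0, false_rate <= 1)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  active <- c(rep(TRUE, A), rep(FALSE, D - A))
  p <- ifelse(active, true_rate, false_rate)
  hit <- stats::runif(D) < p
  out <- data.frame(id = sprintf("cmp%05d", seq_len(D)), active = active,
                    hit = hit, stringsAsFactors = FALSE)
  attr(out, "enrichment") <- enrichment(sum(active & hit), sum(hit), A, D)
  out
}

#' Enrichment of a labeled hit table
#' @param screen data.frame with logical `active` and `hit` columns.
#' @return the [enrichment()] result of the realized counts.
#' @export
enrichment_from_table <- function(screen) {
  enrichment(sum(screen$active & screen$hit), sum(screen$hit),
             sum(screen$active), nrow(screen))
}

#' Synthetic trajectory with known rigid motion and jitter
#'
#' Frames are the reference structure under a per-frame rigid motion
#' (rotation of `drift * (t-1)` degrees about the z axis plus a
#' translation of `drift * (t-1) / 10` nm along x) with isotropic Gaussian
#' jitter of standard deviation `noise` per coordinate. After optimal
#' superposition the expected RMSD of a jittered frame is approximately
#' `noise * sqrt(3 * (1 - 1/n_atoms))` (centering removes one atom's worth
#' of variance per axis); that value is recorded for tests.
#'
#' @param n_atoms atoms.
#' @param n_frames frames.
#' @param drift rigid-motion rate (degrees and nm/10 per frame).
#' @param noise jitter sd in nm.
#' @param seed integer seed.
#' @return a [trajectory()] with attributes `reference` (clean frame) and
#'   `expected_rmsd`.
#' @export
make_trajectory <- function(n_atoms = 100, n_frames = 20, drift = 1,
                            noise = 0.02, seed = 1L) {
  stopifnot(n_atoms >= 4, n_frames >= 1, noise >= 0)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  ref <- matrix(stats::rnorm(n_atoms * 3, sd = 1), n_atoms, 3)
  frames <- lapply(seq_len(n_frames), function(t) {
    th <- (t - 1) * drift * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    ref %*% R + matrix(c((t - 1) * drift / 10, 0, 0), n_atoms, 3,
                       byrow = TRUE) +
      matrix(stats::rnorm(n_atoms * 3, sd = noise), n_atoms, 3)
  })
  traj <- trajectory(frames)
  attr(traj, "reference") <- ref
  attr(traj, "expected_rmsd") <- noise * sqrt(3 * (1 - 1 / n_atoms))
  traj
}

#' @keywords internal
.Random.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
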