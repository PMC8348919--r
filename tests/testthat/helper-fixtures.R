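# Shared test fixtures, built in code.

# a bare-bones conformer from coordinates; property columns optional
toy_conformer <- function(xyz, element = "C", charge = 0, id = "toy", ...) {
  xyz <- matrix(xyz, ncol = 3)
  atoms <- data.frame(element = rep_len(element, nrow(xyz)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = rep_len(charge, nrow(xyz)),
                      stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) atoms[[nm]] <- rep_len(extra[[nm]], nrow(xyz))
  conformer(atoms, compound_id = id)
}

# random rigid motion applied to an n x 3 matrix (seeded by caller)
rigid_motion <- function(xyz, angles = stats::runif(3, 0, 2 * pi),
                         shift = stats::rnorm(3, sd = 5)) {
  Rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), sin(angles[1]),
                 0, -sin(angles[1]), cos(angles[1])), 3, 3)
  Ry <- matrix(c(cos(angles[2]), 0, -sin(angles[2]), 0, 1, 0,
                 sin(angles[2]), 0, cos(angles[2])), 3, 3)
  Rz <- matrix(c(cos(angles[3]), sin(angles[3]), 0,
                 -sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3)
  sweep(as.matrix(xyz) %*% (Rx %*% Ry %*% Rz), 2, shift, "+")
}

# independent squared point-atom distances (loops, no outer-product trick)
point_atom_dist2_oracle <- function(points, xyz) {
  out <- matrix(0, nrow(points), nrow(xyz))
  for (i in seq_len(nrow(points))) for (j in seq_len(nrow(xyz))) {
    out[i, j] <- sum((points[i, ] - xyz[j, ])^2)
  }
  out
}

# 6-12 potential evaluated the direct scalar way (independent of the
# vectorized field path)
lj_scalar <- function(r, r_i, eps_i, r_p, eps_p) {
  R <- r_i + r_p
  eps <- sqrt(eps_i * eps_p)
  eps * ((R / r)^12 - 2 * (R / r)^6)
}
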