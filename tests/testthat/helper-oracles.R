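# Independent oracles and small fixture builders shared across tests.

# Brute-force torsion oracle: project the outer segments onto the plane
# perpendicular to the p2->p3 axis and measure the signed angle between the
# projected rays (positive = clockwise viewed from p2 toward p3). Written
# independently of the package's arctangent formulation.
proj_torsion <- function(p1, p2, p3, p4) {
  u <- p3 - p2
  u <- u / sqrt(sum(u^2))
  a <- (p1 - p2) - sum((p1 - p2) * u) * u
  b <- (p4 - p3) - sum((p4 - p3) * u) * u
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sum(cr * u), sum(a * b)) * 180 / pi
}

# smallest absolute difference between two angles on the circle
ang_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# random proper rotation (QR with determinant fix) and translation
random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(pts, rigid) sweep(pts %*% t(rigid$R), 2, -rigid$t)

# random non-degenerate quadruple of points
random_quadruple <- function(sd = 5) {
  repeat {
    p <- matrix(rnorm(12, sd = sd), 4, 3)
    ok <- tryCatch({
      tmjoint::torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]); TRUE
    }, error = function(e) FALSE)
    if (ok) return(p)
  }
}

# assemble an angle_series directly from an interleaved angle vector
# (omega_1, lambda_1, omega_2, ...), bypassing geometry
series_from_angles <- function(angles, id = "X") {
  k <- seq_along(angles)
  stopifnot(length(angles) >= 1, length(angles) %% 2 == 1)
  n <- (length(angles) + 3) %/% 2
  df <- data.frame(
    protein_id = id,
    kind = ifelse(k %% 2 == 1, "omega", "lambda"),
    index = ifelse(k %% 2 == 1, (k + 1) %/% 2, k %/% 2),
    angle_deg = angles,
    j1 = k, j2 = k + 1, j3 = k + 2, j4 = k + 3,
    stringsAsFactors = FALSE
  )
  structure(df, n_helices = n, class = c("angle_series", "data.frame"))
}

# a randomized bundle spec with torsions away from the +/-180 seam
random_spec <- function(n = NULL, id = "RND") {
  if (is.null(n)) n <- sample(3:8, 1)
  tmjoint::bundle_spec(
    n,
    segment_lengths = runif(2 * n - 1, 6, 32),
    planar_angles = runif(2 * n - 2, 25, 155),
    torsions = runif(2 * n - 3, -179, 179),
    protein_id = id
  )
}

# minimal hand-written PDB text: chain A with CA at given coordinates
tiny_pdb <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                     alt = rep("", nrow(xyz)), occ = rep(1, nrow(xyz))) {
  sprintf("ATOM  %5d  CA %1sALA %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
          seq_len(nrow(xyz)), ifelse(alt == "", " ", alt), chain, resno,
          xyz[, 1], xyz[, 2], xyz[, 3], occ)
}
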