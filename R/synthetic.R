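#' Internal-coordinate recipe for a synthetic joint skeleton
#'
#' A bundle of n helices is described by its 2n joint points; the skeleton is
#' fixed (up to rigid motion) by 2n-1 inter-joint distances `d_i = |P_i
#' P_(i+1)|` (alternating helix span, loop span), 2n-2 planar angles `theta_i`
#' at the interior joints, and 2n-3 torsions `tau_k`, which are exactly the
#' alternating omega/lambda angles the analysis recovers. The recipe is the
#' inverse of torsion measurement and serves as the package's exact oracle.
#'
#' @param n_helices Integer >= 2.
#' @param segment_lengths Numeric, length 2n-1, all > 0 (Angstrom).
#' @param planar_angles Numeric, length 2n-2, strictly inside (0, 180)
#'   degrees (0 or 180 would make the downstream torsion undefined).
#' @param torsions Numeric, length 2n-3, in (-180, 180] degrees; entries
#'   alternate omega, lambda, omega, ... targets.
#' @param protein_id Identifier carried through to the built skeleton.
#' @return A `bundle_spec` object.
#' @export
bundle_spec <- function(n_helices, segment_lengths, planar_angles, torsions,
                        protein_id = "synthetic") {
  n <- as.integer(n_helices)
  if (is.na(n) || n < 2L) stop("n_helices must be an integer >= 2")
  if (length(segment_lengths) != 2L * n - 1L)
    stop("need ", 2L * n - 1L, " segment lengths for ", n, " helices")
  if (length(planar_angles) != 2L * n - 2L)
    stop("need ", 2L * n - 2L, " planar angles for ", n, " helices")
  if (length(torsions) != 2L * n - 3L)
    stop("need ", 2L * n - 3L, " torsions for ", n, " helices")
  if (any(segment_lengths <= 0)) stop("segment lengths must be positive")
  if (any(planar_angles <= 0 | planar_angles >= 180))
    stop("planar angles must lie strictly between 0 and 180 degrees")
  if (any(torsions <= -180 | torsions > 180))
    stop("torsions must lie in (-180, 180]")
  structure(list(protein_id = protein_id, n_helices = n,
                 segment_lengths = as.numeric(segment_lengths),
                 planar_angles = as.numeric(planar_angles),
                 torsions = as.numeric(torsions)),
            class = "bundle_spec")
}

#' @export
print.bundle_spec <- function(x, ...) {
  cat("Bundle spec ", x$protein_id, ": ", x$n_helices, " helices; torsions ",
      paste(sprintf("%.1f", x$torsions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the joint skeleton prescribed by a bundle spec
#'
#' Standard torsion-extension (NeRF) chain building: P_1 at the origin, P_2
#' on +x, P_3 in the xy-plane, and every further point placed from the three
#' preceding ones so that its distance, planar angle and torsion match the
#' spec exactly. By construction `compute_series(build_chain(spec))`
#' reproduces `spec$torsions` to floating-point accuracy.
#'
#' @param spec A [bundle_spec()].
#' @return A `joint_set` of 2n points.
#' @export
build_chain <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  d <- spec$segment_lengths
  th <- spec$planar_angles * pi / 180
  ta <- spec$torsions * pi / 180
  m <- 2L * spec$n_helices
  pts <- matrix(0, nrow = m, ncol = 3L)
  pts[2L, ] <- c(d[1L], 0, 0)
  pts[3L, ] <- pts[2L, ] + d[2L] * c(-cos(th[1L]), sin(th[1L]), 0)
  for (i in seq(4L, m)) {
    pts[i, ] <- nerf_place(pts[i - 3L, ], pts[i - 2L, ], pts[i - 1L, ],
                           d[i - 1L], th[i - 2L], ta[i - 3L])
  }
  joint_set(spec$protein_id, pts)
}

# place D from A,B,C given |CD| = d, angle(B,C,D) = theta, torsion(A,B,C,D) = tau
# (theta, tau in radians); sign chosen to match torsion_angle()'s convention
nerf_place <- function(a, b, c, d, theta, tau) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("cannot extend from a collinear triple")
  n <- n / nn
  m2 <- cross3(n, bc)
  local <- d * c(-cos(theta), sin(theta) * cos(tau), sin(theta) * sin(tau))
  c + local[1L] * bc + local[2L] * m2 + local[3L] * n
}

#' Reflect a joint skeleton through the yz-plane
#'
#' Mirror images negate every torsion angle, so a mirrored cohort is the
#' canonical positive control for lambda-sign symmetry screening.
#'
#' @param joints A `joint_set`.
#' @param protein_id Identifier for the mirrored copy (default: original id
#'   with `"_mir"` appended).
#' @return A `joint_set` with the x coordinate negated.
#' @export
mirror_joints <- function(joints, protein_id = NULL) {
  stopifnot(inherits(joints, "joint_set"))
  if (is.null(protein_id)) protein_id <- paste0(joints$protein_id, "_mir")
  pts <- joints$points
  pts[, 1L] <- -pts[, 1L]
  joint_set(protein_id, pts)
}

#' Write a synthetic helix bundle as PDB text
#'
#' Each helix segment of the skeleton is fleshed out as an ideal alpha-helical
#' CA trace (100 degrees of twist per residue, 2.3 Angstrom radius, rise set
#' by the joint-to-joint span) and loop residues are interpolated linearly at
#' ~3.8 Angstrom spacing. The helix axis is tilted and offset in closed form
#' so that the first and last CA of every helix coincide exactly with the
#' skeleton's joint points; re-reading the file and re-extracting the joints
#' therefore reproduces the prescribed torsions up to coordinate rounding
#' (PDB files store 3 decimals).
#'
#' Matching HELIX header records and a segment-annotation table are produced
#' alongside the coordinates.
#'
#' @param joints A `joint_set` (e.g. from [build_chain()]).
#' @param residues_per_helix Integer >= 4, CA count per helix.
#' @param chain_id Chain letter for the output, default `"A"`.
#' @param file Optional path; when given, the PDB text is written there.
#' @return A list with `pdb` (character vector of PDB lines), `annotation`
#'   (data frame `protein_id`, `chain`, `helix_index`, `start_residue`,
#'   `end_residue`) and `file` (path or `NULL`).
#' @export
write_bundle_pdb <- function(joints, residues_per_helix = 20L, chain_id = "A",
                             file = NULL) {
  stopifnot(inherits(joints, "joint_set"))
  m <- as.integer(residues_per_helix)
  if (is.na(m) || m < 4L) stop("residues_per_helix must be an integer >= 4")
  n <- joints$n_helices
  pts <- joints$points
  coords <- list(); resno <- 0L
  ann <- data.frame(protein_id = character(0), chain = character(0),
                    helix_index = integer(0), start_residue = integer(0),
                    end_residue = integer(0), stringsAsFactors = FALSE)
  helix_rows <- list()
  for (i in seq_len(n)) {
    p <- pts[2L * i - 1L, ]; q <- pts[2L * i, ]
    hx <- ideal_helix_between(p, q, m)
    start_res <- resno + 1L
    end_res <- resno + m
    coords[[length(coords) + 1L]] <- hx
    resno <- end_res
    ann <- rbind(ann, data.frame(protein_id = joints$protein_id,
                                 chain = chain_id, helix_index = i,
                                 start_residue = start_res,
                                 end_residue = end_res,
                                 stringsAsFactors = FALSE))
    helix_rows[[i]] <- c(start_res, end_res)
    if (i < n) {  # loop to the next helix start
      a <- q; b <- pts[2L * i + 1L, ]
      gap <- sqrt(sum((b - a)^2))
      nl <- max(as.integer(round(gap / 3.8)) - 1L, 0L)
      if (nl > 0L) {
        fr <- seq_len(nl) / (nl + 1L)
        coords[[length(coords) + 1L]] <-
          t(vapply(fr, function(f) a + f * (b - a), numeric(3L)))
        resno <- resno + nl
      }
    }
  }
  xyz <- do.call(rbind, coords)
  lines <- character(0)
  for (i in seq_len(n)) {
    hr <- helix_rows[[i]]
    lines <- c(lines, sprintf(
      "HELIX  %3d %3s ALA %1s %4d  ALA %1s %4d %2d %-29s %5d",
      i, sprintf("H%d", i), chain_id, hr[1L], chain_id, hr[2L], 1L, "",
      hr[2L] - hr[1L] + 1L))
  }
  atom <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(xyz)), chain_id, seq_len(nrow(xyz)),
    xyz[, 1L], xyz[, 2L], xyz[, 3L], 1.00, 0.00)
  lines <- c(lines, atom, "END")
  if (!is.null(file)) writeLines(lines, file)
  list(pdb = lines, annotation = ann, file = file)
}

# m CA positions of an ideal helix (100 deg/residue, 2.3 A radius) whose
# first and last CA fall exactly on p and q: the axis is tilted away from the
# p->q chord just enough to absorb the radial offset of the two termini
ideal_helix_between <- function(p, q, m, radius = 2.3, twist_deg = 100) {
  w <- q - p
  d <- sqrt(sum(w^2))
  psi <- twist_deg * pi / 180
  delta <- ((m - 1) * psi) %% (2 * pi)
  cnorm <- 2 * radius * sin(delta / 2)       # |terminal offset difference|
  if (cnorm >= d)
    stop("helix span ", sprintf("%.1f", d),
         " A too short for the terminal-offset construction")
  L <- sqrt(d^2 - cnorm^2)
  w_hat <- w / d
  ref <- if (abs(w_hat[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  qv <- cross3(w_hat, ref)
  qv <- qv / sqrt(sum(qv^2))
  axis <- (L * w_hat - cnorm * qv) / d       # unit: L^2 + cnorm^2 = d^2
  e1 <- (cnorm * w_hat + L * qv) / d         # unit, perpendicular to axis
  e2 <- cross3(axis, e1)
  a0 <- -pi / 2 - delta / 2                  # phase putting CA_1 on p, CA_m on q
  rise <- L / (m - 1)
  j <- seq_len(m) - 1L
  phase <- a0 + j * psi
  origin <- p - radius * (cos(a0) * e1 + sin(a0) * e2)
  t(vapply(seq_len(m), function(k) {
    origin + rise * j[k] * axis +
      radius * (cos(phase[k]) * e1 + sin(phase[k]) * e2)
  }, numeric(3L)))
}

#' Generate a reproducible cohort of synthetic bundle specs
#'
#' Emulates the dihedral structure seen in polytopic membrane proteins:
#' omega-type torsions (adjacent-helix tilt) are concentrated in a slightly
#' slanted anti-parallel band, drawn by default as an equal mixture of
#' uniform(-40, -10) and uniform(+10, +40) degrees, while lambda-type
#' torsions are uniform over (-180, 180]. Helix spans, loop spans and planar
#' angles are drawn from ranges typical of membrane-embedded bundles.
#'
#' @param n_proteins Integer >= 1.
#' @param tm_range Length-2 integer vector, inclusive range of helix counts
#'   per protein (default 3 to 6).
#' @param angle_model List with entries `omega` (length-2, magnitude range in
#'   degrees, sign randomized) and `lambda` (length-2 range in degrees).
#' @param helix_span,loop_span Length-2 ranges (Angstrom) for joint-to-joint
#'   helix and loop distances.
#' @param planar_range Length-2 range (degrees) for the planar angles.
#' @param seed Integer seed; the cohort is a pure function of its arguments.
#' @return A list of `bundle_spec` objects with ids `SYN001`, `SYN002`, ...
#' @export
generate_cohort <- function(n_proteins, tm_range = c(3L, 6L),
                            angle_model = list(omega = c(10, 40),
                                               lambda = c(-180, 180)),
                            helix_span = c(26, 32), loop_span = c(9, 14),
                            planar_range = c(60, 120), seed = 1L) {
  stopifnot(n_proteins >= 1L, length(tm_range) == 2L,
            tm_range[1L] >= 2L, tm_range[1L] <= tm_range[2L])
  set.seed(as.integer(seed))
  choices <- seq(tm_range[1L], tm_range[2L])
  lapply(seq_len(n_proteins), function(i) {
    n <- choices[sample.int(length(choices), 1L)]
    n_tor <- 2L * n - 3L
    is_omega <- seq_len(n_tor) %% 2L == 1L
    tor <- numeric(n_tor)
    n_om <- sum(is_omega)
    tor[is_omega] <- sample(c(-1, 1), n_om, replace = TRUE) *
      stats::runif(n_om, angle_model$omega[1L], angle_model$omega[2L])
    tor[!is_omega] <- stats::runif(n_tor - n_om,
                                   angle_model$lambda[1L], angle_model$lambda[2L])
    seg <- numeric(2L * n - 1L)
    seg[seq(1L, 2L * n - 1L, by = 2L)] <-
      stats::runif(n, helix_span[1L], helix_span[2L])
    if (n > 1L)
      seg[seq(2L, 2L * n - 2L, by = 2L)] <-
        stats::runif(n - 1L, loop_span[1L], loop_span[2L])
    bundle_spec(n, seg,
                stats::runif(2L * n - 2L, planar_range[1L], planar_range[2L]),
                tor, protein_id = sprintf("SYN%03d", i))
  })
}
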