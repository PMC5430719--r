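#' Signed torsion angle of four points
#'
#' Computes the signed dihedral angle defined by four points, i.e. the angle
#' between the plane through (`p1`, `p2`, `p3`) and the plane through
#' (`p2`, `p3`, `p4`), measured about the `p2`-`p3` axis.
#'
#' The right-handed two-argument arctangent formulation is used: with bond
#' vectors `b1 = p2 - p1`, `b2 = p3 - p2`, `b3 = p4 - p3` and plane normals
#' `n1 = b1 x b2`, `n2 = b2 x b3`, the angle is
#' `atan2((n1 x n2) . b2_hat, n1 . n2)`. Under this convention a positive
#' angle corresponds to a clockwise rotation of the far segment relative to
#' the near segment when the quadruple is projected onto the plane
#' perpendicular to the `p2`-`p3` axis and viewed from `p2` toward `p3`.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Cartesian coordinates, typically in
#'   Angstrom; the torsion is scale-free).
#' @return The torsion angle in degrees, in the half-open interval
#'   (-180, 180]; an exact trans configuration is reported as +180.
#' @examples
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   #   0 (cis)
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180 (trans)
#' @seealso [compute_series()] for the alternating omega/lambda series of a
#'   joint skeleton.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  pts <- rbind(as.numeric(p1), as.numeric(p2), as.numeric(p3), as.numeric(p4))
  if (ncol(pts) != 3L || anyNA(pts))
    stop("torsion_angle() requires four finite 3-vectors")
  b1 <- pts[2L, ] - pts[1L, ]
  b2 <- pts[3L, ] - pts[2L, ]
  b3 <- pts[4L, ] - pts[3L, ]
  len <- c(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2)))
  if (any(len < .Machine$double.eps * 100))
    stop("degenerate segment: two consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  # collinear triple => vanishing normal; tolerance relative to segment lengths
  if (sqrt(sum(n1^2)) < 1e-10 * len[1L] * len[2L] ||
      sqrt(sum(n2^2)) < 1e-10 * len[2L] * len[3L])
    stop("undefined normal: three consecutive points are collinear")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / len[2L]
  wrap_angle(atan2(y, x) * 180 / pi)
}

# cross product, 3-vectors only
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# map into (-180, 180]; exact -180 becomes +180 (single trans representative)
wrap_angle <- function(deg) {
  out <- deg - 360 * floor((deg + 180) / 360)
  out[out <= -180] <- 180
  out
}

#' Alternating omega/lambda torsion series of a joint skeleton
#'
#' Slides a four-point window along the 2n joint points of an n-helix bundle
#' and computes each signed torsion. Window k uses joints P_k..P_(k+3); odd k
#' starts at a helix-begin joint and yields an omega-type angle
#' (helix-loop-helix, relative tilt of helices i and i+1), even k starts at a
#' helix-end joint and yields a lambda-type angle (loop-helix-loop, placement
#' of helix i+2 relative to helix i). A bundle with n helices therefore has
#' exactly n-1 omega and n-2 lambda angles, interleaved as
#' omega_1, lambda_1, omega_2, lambda_2, ...
#'
#' @param joints A `joint_set` from [extract_joints()] or [build_chain()], or
#'   a plain 2n-by-3 numeric matrix of joint coordinates.
#' @param protein_id Identifier stored in the result; defaults to the id
#'   carried by `joints`.
#' @return An `angle_series`: a data frame with columns `protein_id`, `kind`
#'   (`"omega"` or `"lambda"`), `index` (1-based within kind), `angle_deg`,
#'   and the four joint positions `j1`..`j4`, plus attribute `n_helices`.
#' @examples
#' sp <- bundle_spec(n_helices = 3, segment_lengths = rep(10, 5),
#'                   planar_angles = rep(90, 4), torsions = c(25, -120, 25))
#' compute_series(build_chain(sp))
#' @export
compute_series <- function(joints, protein_id = NULL) {
  pts <- joint_matrix(joints)
  if (is.null(protein_id))
    protein_id <- attr(joints, "protein_id") %||% "unknown"
  m <- nrow(pts)
  if (m %% 2L != 0L || m < 4L)
    stop("a joint set must contain 2n points with n >= 2 helices, got ", m)
  n <- m %/% 2L
  if (n == 2L)
    warning("only 2 helices: a single omega angle and no lambda angles")
  k <- seq_len(m - 3L)
  ang <- vapply(k, function(i) {
    tryCatch(
      torsion_angle(pts[i, ], pts[i + 1L, ], pts[i + 2L, ], pts[i + 3L, ]),
      error = function(e) stop(protein_id, ", window ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  }, numeric(1L))
  out <- data.frame(
    protein_id = protein_id,
    kind = ifelse(k %% 2L == 1L, "omega", "lambda"),
    index = ifelse(k %% 2L == 1L, (k + 1L) %/% 2L, k %/% 2L),
    angle_deg = ang,
    j1 = k, j2 = k + 1L, j3 = k + 2L, j4 = k + 3L,
    stringsAsFactors = FALSE
  )
  structure(out, n_helices = n, class = c("angle_series", "data.frame"))
}

#' Expected omega/lambda angle counts for an n-helix bundle
#'
#' An n-helix topology has 2n joints and 2n-3 four-joint windows: n-1 of
#' omega type and n-2 of lambda type. These counts underpin the per-group
#' accounting of cohort tables (e.g. 9 three-helix proteins carry 18 omega
#' and 9 lambda angles).
#'
#' @param n_helices Integer (vector allowed), number of TM helices, >= 2.
#' @return A data frame with columns `n_helices`, `n_omega`, `n_lambda`.
#' @examples
#' expected_counts(c(3, 14))
#' @export
expected_counts <- function(n_helices) {
  n <- as.integer(n_helices)
  if (length(n) == 0L || anyNA(n) || any(n < 2L))
    stop("n_helices must be integers >= 2")
  data.frame(n_helices = n, n_omega = n - 1L, n_lambda = pmax(n - 2L, 0L))
}

#' @export
print.angle_series <- function(x, ...) {
  cat("Joint torsion series for ", x$protein_id[1L], ": ",
      attr(x, "n_helices"), " helices, ",
      sum(x$kind == "omega"), " omega + ", sum(x$kind == "lambda"),
      " lambda angles\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# accept joint_set or bare matrix
joint_matrix <- function(joints) {
  if (inherits(joints, "joint_set")) return(joints$points)
  m <- as.matrix(joints)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L) stop("joint coordinates must be an m-by-3 matrix")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an angle series (or several) to TSV
#'
#' Columns: `protein_id  kind  index  angle_deg  j1  j2  j3  j4`, with angles
#' at one decimal place (full precision is kept in memory only).
#'
#' @param series An `angle_series` or a list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_angles_tsv <- function(series, file) {
  if (inherits(series, "angle_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  df$angle_deg <- sprintf("%.1f", df$angle_deg)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an angle-series TSV written by [write_angles_tsv()]
#'
#' @param file Input path.
#' @return A list of `angle_series`, one per protein, in file order.
#' @export
read_angles_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "index", "angle_deg")
  if (!all(need %in% names(df)))
    stop("angle TSV must contain columns: ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$protein_id, levels = unique(df$protein_id))),
         function(d) {
           d <- d[order(pmin(d$j1, Inf)), , drop = FALSE]
           n <- sum(d$kind == "omega") + 1L
           structure(d, n_helices = n, class = c("angle_series", "data.frame"))
         })
}
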