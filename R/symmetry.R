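#' Lambda-sign signature of a protein
#'
#' The ordered vector of signs of the lambda-type angles
#' (lambda_1 .. lambda_(n-2)) is a compact fingerprint of how the bundle
#' zig-zags: mirror-image structures have elementwise-negated signatures.
#'
#' @param series An `angle_series`.
#' @return Character vector over `{"+", "-"}`, length n-2.
#' @export
lambda_signature <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  if (attr(series, "n_helices") < 3L)
    stop("protein '", series$protein_id[1L],
         "': lambda angles require at least 3 helices")
  kind_sequence(series, "lambda", "sign")
}

#' Screen a cohort for mirror-image lambda-sign pairs
#'
#' Finds every unordered pair of proteins with the same helix count whose
#' lambda-sign signatures are exact elementwise negations of each other —
#' the computational screen for candidate symmetric (mirror-related) bundle
#' arrangements. Candidates are meant for downstream structural review; a
#' matching signature does not by itself prove 3-D mirror symmetry.
#'
#' @param cohort List of `angle_series` (proteins with fewer than 3 helices
#'   are skipped — they carry no lambda angles).
#' @param mode `"negated"` (default): signature_b is the elementwise sign
#'   flip of signature_a. `"reversed-negated"`: additionally reverses the
#'   order, pairing bundles mirrored end-to-end.
#' @return A data frame `protein_a`, `protein_b`, `n_helices`,
#'   `signature_a`, `signature_b` (signatures comma-joined), each unordered
#'   pair emitted once with `protein_a < protein_b`, sorted lexicographically.
#' @export
find_symmetric_candidates <- function(cohort, mode = c("negated",
                                                       "reversed-negated")) {
  mode <- match.arg(mode)
  if (length(cohort) == 0L) stop("empty cohort")
  cohort <- Filter(function(s) attr(s, "n_helices") >= 3L, cohort)
  ids <- vapply(cohort, function(s) s$protein_id[1L], character(1L))
  ns <- vapply(cohort, function(s) as.integer(attr(s, "n_helices")), integer(1L))
  sigs <- lapply(cohort, lambda_signature)
  out <- data.frame(protein_a = character(0), protein_b = character(0),
                    n_helices = integer(0), signature_a = character(0),
                    signature_b = character(0), stringsAsFactors = FALSE)
  flip <- function(s) ifelse(s == "+", "-", "+")
  m <- length(cohort)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        if (ns[i] != ns[j]) next
        target <- if (mode == "negated") flip(sigs[[i]]) else rev(flip(sigs[[i]]))
        if (!identical(target, sigs[[j]])) next
        a <- order(c(ids[i], ids[j]))
        pair <- c(ids[i], ids[j])[a]
        sg <- list(sigs[[i]], sigs[[j]])[a]
        out <- rbind(out, data.frame(
          protein_a = pair[1L], protein_b = pair[2L], n_helices = ns[i],
          signature_a = paste(sg[[1L]], collapse = ","),
          signature_b = paste(sg[[2L]], collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[!duplicated(out[, c("protein_a", "protein_b")]), , drop = FALSE]
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Per-pair angle table for human review of symmetry candidates
#'
#' @param pair One row of the data frame from [find_symmetric_candidates()].
#' @param cohort The cohort the pair was found in.
#' @return Data frame with both proteins' omega and lambda angles side by
#'   side (`kind`, `index`, `angle_a_deg`, `angle_b_deg`).
#' @export
symmetry_pair_table <- function(pair, cohort) {
  ids <- vapply(cohort, function(s) s$protein_id[1L], character(1L))
  a <- cohort[[match(pair$protein_a, ids)]]
  b <- cohort[[match(pair$protein_b, ids)]]
  if (is.null(a) || is.null(b)) stop("pair members not found in cohort")
  data.frame(kind = a$kind, index = a$index,
             angle_a_deg = round(a$angle_deg, 1),
             angle_b_deg = round(b$angle_deg, 1))
}
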