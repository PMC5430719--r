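#' Read the C-alpha trace of one chain from a PDB file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()] and keeps one CA atom
#' per residue of the requested chain. Alternate locations are resolved to a
#' single conformer: altloc `' '` or `'A'` is preferred, with the
#' highest-occupancy record breaking remaining ties. Residues are keyed by
#' author residue number plus insertion code and kept in file order.
#'
#' @param pdb Path to a PDB file, or a character string of PDB text (detected
#'   by an embedded newline).
#' @param chain_id Single chain identifier, e.g. `"A"`.
#' @return A `calpha_trace`: data frame with columns `resno`, `insert`
#'   (empty string when absent), `x`, `y`, `z`; attribute `chain_id`.
#' @export
read_calpha_coordinates <- function(pdb, chain_id) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  path <- as_pdb_path(pdb)
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!chain_id %in% ca$chain) {
    stop("chain '", chain_id, "' not found; available chains with CA atoms: ",
         paste(sort(unique(ca$chain)), collapse = ", "))
  }
  ca <- ca[ca$chain == chain_id, , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms on chain '", chain_id, "'")
  key <- paste(ca$resno, ca$insert, sep = "|")
  pick <- vapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
                 function(idx) {
                   if (length(idx) == 1L) return(idx)
                   sub <- ca[idx, , drop = FALSE]
                   pref <- idx[sub$alt %in% c("", "A")]
                   if (length(pref)) idx <- pref
                   occ <- ca$o[idx]
                   occ[is.na(occ)] <- 0
                   idx[which.max(occ)]
                 }, integer(1L))
  ca <- ca[sort(pick), , drop = FALSE]
  out <- data.frame(resno = ca$resno, insert = ca$insert,
                    x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
  structure(out, chain_id = chain_id, class = c("calpha_trace", "data.frame"))
}

# accept a file path or raw PDB text
as_pdb_path <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb))
    return(pdb)
  tf <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE)), tf)
  tf
}

#' Read a TM-segment annotation table
#'
#' The table is the reproducible record of where each membrane-spanning helix
#' begins and ends (OPM/PDBTM-style boundaries), tab- or whitespace-separated
#' with header columns `protein_id`, `chain`, `helix_index`, `start_residue`,
#' `end_residue`.
#'
#' @param file Path to the table, or its text content.
#' @return A named list of `protein_topology` objects (one per `protein_id`,
#'   in first-appearance order), each with fields `protein_id`, `chain_id`
#'   and a data frame `segments` (`index`, `start_residue`, `end_residue`)
#'   sorted by start residue.
#' @export
read_segment_annotation <- function(file) {
  path <- if (length(file) == 1L && !grepl("\n", file, fixed = TRUE) &&
              file.exists(file)) file else {
    tf <- tempfile(fileext = ".tsv"); writeLines(file, tf); tf
  }
  df <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(protein_id = "character",
                                         chain = "character"))
  need <- c("protein_id", "chain", "helix_index", "start_residue", "end_residue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  by_prot <- split(df, factor(df$protein_id, levels = unique(df$protein_id)))
  lapply(by_prot, function(d) {
    chains <- unique(d$chain)
    if (length(chains) != 1L)
      stop("protein '", d$protein_id[1L], "': one chain per topology required, got ",
           paste(chains, collapse = ", "))
    protein_topology(
      protein_id = d$protein_id[1L], chain_id = chains,
      start = d$start_residue[order(d$helix_index)],
      end = d$end_residue[order(d$helix_index)]
    )
  })
}

#' Construct a TM-helix topology
#'
#' @param protein_id Identifier, conventionally PDB id + chain (`"3QNQA"`).
#' @param chain_id Chain letter the segments refer to.
#' @param start,end Integer vectors of helix start/end author residue numbers,
#'   in helix order.
#' @return A `protein_topology` object. Segments must satisfy start < end,
#'   be sorted along the sequence and not overlap. Fewer than 2 helices is an
#'   error; exactly 2 (a single omega angle, no lambda) raises a warning.
#' @export
protein_topology <- function(protein_id, chain_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  n <- length(start)
  if (n != length(end)) stop("start and end lengths differ")
  if (n < 2L)
    stop("protein '", protein_id, "': at least 2 TM helices required (got ", n, ")")
  if (any(start >= end))
    stop("protein '", protein_id, "': helix start must precede end (helix ",
         paste(which(start >= end), collapse = ","), ")")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(start[-1L] <= end[-n]))
    stop("protein '", protein_id, "': overlapping helix segments")
  if (n == 2L)
    warning("protein '", protein_id,
            "': only 2 helices; a single omega angle will be computed")
  structure(
    list(protein_id = protein_id, chain_id = chain_id,
         segments = data.frame(index = seq_len(n), start_residue = start,
                               end_residue = end)),
    class = "protein_topology")
}

#' @export
print.protein_topology <- function(x, ...) {
  cat("TM topology ", x$protein_id, " (chain ", x$chain_id, "): ",
      nrow(x$segments), " helices\n", sep = "")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Extract TM-helix segments from PDB HELIX records
#'
#' Fallback annotation source when no segment table is supplied: each HELIX
#' record of the requested chain becomes one segment using the record's
#' initial and terminal residue numbers. Records that do not parse are
#' skipped with a warning. A user-supplied annotation table always takes
#' precedence over this path.
#'
#' @inheritParams read_calpha_coordinates
#' @return A data frame of segments (`index`, `start_residue`,
#'   `end_residue`), possibly with zero rows when the header carries no
#'   HELIX records for the chain.
#' @export
read_helix_records <- function(pdb, chain_id) {
  path <- as_pdb_path(pdb)
  lines <- readLines(path, warn = FALSE)
  hx <- lines[startsWith(lines, "HELIX ")]
  start <- integer(0); end <- integer(0)
  for (ln in hx) {
    # PDB v3.3 fixed columns: initChainID 20, initSeqNum 22-25,
    # endChainID 32, endSeqNum 34-37
    ini_ch <- substr(ln, 20L, 20L)
    end_ch <- substr(ln, 32L, 32L)
    ini <- suppressWarnings(as.integer(substr(ln, 22L, 25L)))
    fin <- suppressWarnings(as.integer(substr(ln, 34L, 37L)))
    if (is.na(ini) || is.na(fin) || ini_ch == "" || ini_ch != end_ch) {
      warning("skipping malformed HELIX record: ", trimws(ln))
      next
    }
    if (ini_ch != chain_id) next
    start <- c(start, ini); end <- c(end, fin)
  }
  data.frame(index = seq_along(start), start_residue = start,
             end_residue = end)
}

#' Assemble the joint-point skeleton of a chain
#'
#' The joints of an n-helix topology are the CA atoms of the first and last
#' residue of each helix, in helix order: P_1 = CA(start of H_1),
#' P_2 = CA(end of H_1), P_3 = CA(start of H_2), and so on, 2n points in
#' total. Boundary residues are matched on residue number with empty
#' insertion code; a missing boundary residue is an error (no silent
#' substitution by a neighbouring residue).
#'
#' @param trace A `calpha_trace` from [read_calpha_coordinates()].
#' @param topology A `protein_topology`.
#' @return A `joint_set`: list with `protein_id`, `n_helices` and `points`,
#'   a 2n-by-3 coordinate matrix.
#' @export
extract_joints <- function(trace, topology) {
  stopifnot(inherits(trace, "calpha_trace"), inherits(topology, "protein_topology"))
  seg <- topology$segments
  n <- nrow(seg)
  resnos <- as.vector(t(seg[, c("start_residue", "end_residue")]))
  pts <- matrix(NA_real_, nrow = 2L * n, ncol = 3L)
  for (i in seq_along(resnos)) {
    hit <- which(trace$resno == resnos[i] & trace$insert == "")
    if (length(hit) != 1L) {
      stop("protein '", topology$protein_id, "', helix ", (i + 1L) %/% 2L,
           ": boundary residue ", resnos[i], " not present in the CA trace")
    }
    pts[i, ] <- c(trace$x[hit], trace$y[hit], trace$z[hit])
  }
  joint_set(topology$protein_id, pts)
}

#' Construct a joint set
#'
#' @param protein_id Identifier.
#' @param points 2n-by-3 numeric matrix of joint coordinates (Angstrom).
#' @return A `joint_set` object.
#' @export
joint_set <- function(protein_id, points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) %% 2L != 0L || nrow(points) < 4L)
    stop("a joint set needs a 2n-by-3 matrix with n >= 2")
  structure(list(protein_id = protein_id, n_helices = nrow(points) %/% 2L,
                 points = points),
            protein_id = protein_id, class = "joint_set")
}

#' @export
print.joint_set <- function(x, ...) {
  cat("Joint set ", x$protein_id, ": ", x$n_helices, " helices, ",
      nrow(x$points), " joint points\n", sep = "")
  invisible(x)
}

#' Write joint sets to the TSV interchange format
#'
#' Columns `protein_id  point_index  x  y  z`, coordinates at 3 decimal
#' places (PDB precision).
#'
#' @param joints A `joint_set` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_joints_tsv <- function(joints, file) {
  if (inherits(joints, "joint_set")) joints <- list(joints)
  rows <- do.call(rbind, lapply(joints, function(j) {
    data.frame(protein_id = j$protein_id,
               point_index = seq_len(nrow(j$points)),
               x = sprintf("%.3f", j$points[, 1L]),
               y = sprintf("%.3f", j$points[, 2L]),
               z = sprintf("%.3f", j$points[, 3L]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read joint sets back from the TSV interchange format
#'
#' @param file Path written by [write_joints_tsv()].
#' @return A list of `joint_set` objects in file order.
#' @export
read_joints_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = c(protein_id = "character"))
  lapply(split(df, factor(df$protein_id, levels = unique(df$protein_id))),
         function(d) {
           d <- d[order(d$point_index), , drop = FALSE]
           joint_set(d$protein_id[1L], cbind(d$x, d$y, d$z))
         })
}
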