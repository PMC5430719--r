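#' Sign category of a dihedral angle
#'
#' Positive angles (clockwise, 0 to 180) map to `"+"`, negative angles
#' (counter-clockwise, 0 to -180) to `"-"`. An exact zero is a measure-zero
#' boundary case and is assigned `"+"` with a warning.
#'
#' @param angle_deg Numeric vector of angles in (-180, 180].
#' @return Character vector over `{"+", "-"}`.
#' @export
sign_of <- function(angle_deg) {
  check_angle_range(angle_deg)
  if (any(angle_deg == 0))
    warning("angle of exactly 0 degrees assigned to '+' by the boundary rule")
  ifelse(angle_deg >= 0, "+", "-")
}

#' Quadrant category of a lambda-type dihedral angle
#'
#' The angle space is split into four 90-degree regions: `A` = (0, 90],
#' `B` = (90, 180], `-A` = [-90, 0), `-B` = (-180, -90). Edges are closed on
#' the side away from zero so that each angle has exactly one label; an exact
#' zero falls into `A` (consistent with [sign_of()]'s boundary rule) with a
#' warning.
#'
#' @inheritParams sign_of
#' @return Character vector over `{"A", "B", "-A", "-B"}`.
#' @export
classify_quadrant <- function(angle_deg) {
  check_angle_range(angle_deg)
  if (any(angle_deg == 0))
    warning("angle of exactly 0 degrees assigned to 'A' by the boundary rule")
  ifelse(angle_deg > 90, "B",
         ifelse(angle_deg >= 0, "A",
                ifelse(angle_deg >= -90, "-A", "-B")))
}

check_angle_range <- function(angle_deg) {
  if (any(is.na(angle_deg)) || any(angle_deg <= -180 | angle_deg > 180))
    stop("angles must lie in (-180, 180]")
}

#' Overlapping k-windows of a category sequence
#'
#' Enumerates every run of `k` consecutive entries, in order; only adjacent
#' same-kind angles form a window (there is no skipping over positions).
#'
#' @param x Character vector of categories (signs or quadrant labels).
#' @param k Window length, 2 (dyads) or 3 (triads).
#' @return Character vector of patterns, each a comma-joined k-tuple such as
#'   `"+,-"`; empty when `length(x) < k`.
#' @export
consecutive_patterns <- function(x, k) {
  k <- as.integer(k)
  if (!k %in% c(2L, 3L)) stop("window length k must be 2 or 3")
  n <- length(x)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1L),
         function(i) paste(x[i:(i + k - 1L)], collapse = ","),
         character(1L))
}

sign_alphabet <- c("+", "-")
quadrant_alphabet <- c("A", "B", "-A", "-B")

# all k-tuples over an alphabet, zero-filled count template
pattern_space <- function(alphabet, k) {
  grids <- rev(do.call(expand.grid,
                       c(rep(list(alphabet), k),
                         list(stringsAsFactors = FALSE))))
  apply(as.matrix(grids[, rev(seq_len(k)), drop = FALSE]), 1L, paste,
        collapse = ",")
}

# per-protein category sequence of one kind from an angle series
kind_sequence <- function(series, kind, alphabet = c("sign", "quadrant")) {
  alphabet <- match.arg(alphabet)
  a <- series$angle_deg[series$kind == kind][order(series$index[series$kind == kind])]
  if (alphabet == "sign") sign_of(a) else classify_quadrant(a)
}

#' Count consecutive dihedral-angle patterns across a cohort
#'
#' Converts each protein's omega- or lambda-angle series into sign (or, for
#' lambda, quadrant) categories, enumerates all adjacent k-windows, and pools
#' the counts over proteins. Every possible pattern is present in the result,
#' zero-filled, so dyad sign counts always have 4 entries, triads 8, and
#' lambda quadrant dyads 16. Optionally the cohort is partitioned into
#' TM-size groups first and one count table is returned per group.
#'
#' @param series_collection List of `angle_series`.
#' @param kind `"omega"` or `"lambda"`.
#' @param k Window length, 2 or 3.
#' @param alphabet `"sign"` (default) or `"quadrant"`; quadrant categories
#'   are defined for lambda angles only.
#' @param groups Optional list of inclusive helix-count bins, e.g.
#'   `list(c(3, 6), c(7, 10), c(11, 14))` (see [tm_size_groups()]); proteins
#'   outside every bin are dropped.
#' @param bootstrap_B If not `NULL`, number of bootstrap replicates for
#'   per-pattern standard deviations (the cohort's window-level observations
#'   are resampled with replacement; see [bootstrap_sd()]).
#' @param seed Seed for the bootstrap.
#' @return A `pattern_counts` object, or a named list of them (one per
#'   group). Each holds `counts` and optionally `bootstrap_sd`, both named
#'   by pattern.
#' @export
count_patterns <- function(series_collection, kind = c("omega", "lambda"),
                           k = 2L, alphabet = c("sign", "quadrant"),
                           groups = NULL, bootstrap_B = NULL, seed = 1L) {
  kind <- match.arg(kind)
  alphabet <- match.arg(alphabet)
  if (alphabet == "quadrant" && kind == "omega")
    stop("quadrant categories are defined for lambda angles only")
  if (inherits(series_collection, "angle_series"))
    series_collection <- list(series_collection)
  if (is.null(groups)) {
    return(count_patterns_one(series_collection, kind, k, alphabet,
                              NULL, bootstrap_B, seed))
  }
  out <- lapply(groups, function(g) {
    members <- Filter(function(s) {
      n <- attr(s, "n_helices"); n >= g[1L] && n <= g[2L]
    }, series_collection)
    count_patterns_one(members, kind, k, alphabet,
                       sprintf("%d-%d TM", g[1L], g[2L]), bootstrap_B, seed)
  })
  names(out) <- vapply(groups, function(g) sprintf("%d-%d TM", g[1L], g[2L]),
                       character(1L))
  out
}

count_patterns_one <- function(series_list, kind, k, alphabet, group_label,
                               bootstrap_B, seed) {
  space <- pattern_space(if (alphabet == "sign") sign_alphabet else
                           quadrant_alphabet, k)
  obs <- unlist(lapply(series_list, function(s)
    consecutive_patterns(kind_sequence(s, kind, alphabet), k)))
  counts <- table(factor(obs, levels = space))
  counts <- stats::setNames(as.integer(counts), space)
  sds <- NULL
  if (!is.null(bootstrap_B)) {
    # an empty pool (e.g. an unpopulated TM-size group) has exactly zero
    # counts with no resampling variability
    sds <- if (length(obs) == 0L) stats::setNames(rep(0, length(space)), space)
           else bootstrap_sd(obs, patterns = space, B = bootstrap_B, seed = seed)
  }
  structure(list(window = as.integer(k), alphabet = alphabet, kind = kind,
                 counts = counts, bootstrap_sd = sds,
                 group_label = group_label, n_observations = length(obs)),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Consecutive ", x$kind, " patterns (", x$alphabet, " alphabet, k = ",
      x$window, if (!is.null(x$group_label)) paste0(", group ", x$group_label),
      "): ", x$n_observations, " windows\n", sep = "")
  df <- data.frame(pattern = names(x$counts), count = unname(x$counts))
  if (!is.null(x$bootstrap_sd)) df$bootstrap_sd <- round(unname(x$bootstrap_sd), 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bootstrap standard deviations of pattern counts
#'
#' Resamples the window-level observations with replacement to the original
#' sample size, re-tallies each replicate, and reports the per-pattern
#' standard deviation of the replicate counts. A pattern that never occurs
#' has SD 0 (it is never drawn).
#'
#' @param observations Character vector of observed patterns (one entry per
#'   window).
#' @param patterns Optional full pattern space for zero-filling; defaults to
#'   the distinct observed patterns.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return Named numeric vector of standard deviations.
#' @export
bootstrap_sd <- function(observations, patterns = NULL, B = 500L, seed = 1L) {
  if (length(observations) == 0L) stop("no observations to resample")
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be >= 1")
  if (is.null(patterns)) patterns <- sort(unique(observations))
  f <- factor(observations, levels = patterns)
  n <- length(observations)
  set.seed(as.integer(seed))
  tallies <- vapply(seq_len(B), function(b)
    tabulate(f[sample.int(n, n, replace = TRUE)], nbins = length(patterns)),
    integer(length(patterns)))
  sds <- apply(matrix(tallies, nrow = length(patterns)), 1L, stats::sd)
  stats::setNames(sds, patterns)
}

#' Default TM-size groups
#'
#' Cohorts are conventionally compared across small (3-6 helices), medium
#' (7-10) and large (11-14) bundles.
#'
#' @return A list of inclusive `c(min, max)` helix-count bins.
#' @export
tm_size_groups <- function() list(c(3L, 6L), c(7L, 10L), c(11L, 14L))

#' Angle distributions of a cohort
#'
#' Summarises a collection of angle series three ways: (i) scatter pairs
#' `(omega_i, lambda_i)` within each protein — the two angles of a pair share
#' three of their four joints; (ii) marginal histograms of all omega and all
#' lambda angles at a fixed bin width aligned to 0; (iii) per-position pools
#' (all omega_1 together, all omega_2, ...). The fraction of omega angles
#' inside a query range is also reported (the anti-parallel band is
#' conventionally taken as -40 to +40 degrees).
#'
#' @param series_collection List of `angle_series` (or a single one).
#' @param bin_width Histogram bin width in degrees; must divide 360
#'   (default 20).
#' @param omega_range Length-2 numeric, inclusive query range for the omega
#'   fraction (default `c(-40, 40)`).
#' @return A list with `scatter` (data frame `protein_id`, `index`,
#'   `omega_deg`, `lambda_deg`), `histogram` (data frame `bin_low`,
#'   `bin_high`, `count`, `kind`; bins are (low, high]), `per_position`
#'   (data frame `kind`, `index`, `angle_deg`), `omega_fraction_in_range`
#'   and `omega_range`.
#' @export
angle_distributions <- function(series_collection, bin_width = 20,
                                omega_range = c(-40, 40)) {
  if (inherits(series_collection, "angle_series"))
    series_collection <- list(series_collection)
  if (length(series_collection) == 0L) stop("empty series collection")
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  scatter <- do.call(rbind, lapply(series_collection, function(s) {
    om <- s[s$kind == "omega", ]; la <- s[s$kind == "lambda", ]
    idx <- intersect(om$index, la$index)
    if (length(idx) == 0L) return(NULL)
    data.frame(protein_id = s$protein_id[1L], index = sort(idx),
               omega_deg = om$angle_deg[match(sort(idx), om$index)],
               lambda_deg = la$angle_deg[match(sort(idx), la$index)],
               stringsAsFactors = FALSE)
  }))
  pooled <- do.call(rbind, lapply(series_collection, as.data.frame))
  breaks <- seq(-180, 180, by = bin_width)
  hist_df <- do.call(rbind, lapply(c("omega", "lambda"), function(kd) {
    a <- pooled$angle_deg[pooled$kind == kd]
    cnt <- as.integer(table(cut(a, breaks = breaks, right = TRUE,
                                include.lowest = FALSE)))
    data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1L],
               count = cnt, kind = kd, stringsAsFactors = FALSE)
  }))
  per_pos <- pooled[order(pooled$kind, pooled$index),
                    c("kind", "index", "angle_deg")]
  om <- pooled$angle_deg[pooled$kind == "omega"]
  frac <- if (length(om)) mean(om >= omega_range[1L] & om <= omega_range[2L])
          else NA_real_
  list(scatter = scatter, histogram = hist_df, per_position = per_pos,
       omega_fraction_in_range = frac, omega_range = omega_range)
}

#' Write one or more pattern-count tables to TSV
#'
#' Columns: `pattern  count  bootstrap_sd  group` (`bootstrap_sd` is `NA`
#' when no bootstrap was run, `group` is `"all"` for ungrouped counts).
#'
#' @param x A `pattern_counts` or a list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_patterns_tsv <- function(x, file) {
  if (inherits(x, "pattern_counts")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(pc) {
    data.frame(pattern = names(pc$counts), count = unname(pc$counts),
               bootstrap_sd = if (is.null(pc$bootstrap_sd)) NA_real_
                              else round(unname(pc$bootstrap_sd), 4),
               group = pc$group_label %||% "all", stringsAsFactors = FALSE)
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
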