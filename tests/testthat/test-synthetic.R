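test_that("a planar right-angle chain builds coplanar points with zero torsions", {
  sp <- bundle_spec(3, rep(10, 5), rep(90, 4), c(0.0000001, 0.0000001, 0.0000001))
  js <- build_chain(sp)
  expect_equal(nrow(js$points), 6L)
  expect_lt(max(abs(js$points[, 3])), 1e-6)  # stays in the xy-plane
  expect_lt(max(abs(compute_series(js)$angle_deg)), 1e-5)
})

test_that("prescribed torsions are recovered exactly on the skeleton", {
  sp <- bundle_spec(3, rep(10, 5), rep(80, 4), c(25, -120, 25))
  expect_lt(max(abs(compute_series(build_chain(sp))$angle_deg -
                      c(25, -120, 25))), 1e-6)
})

test_that("distances, planar angles and torsions all round-trip", {
  set.seed(55)
  worst_t <- worst_d <- worst_a <- 0
  for (r in 1:100) {
    sp <- random_spec()
    pts <- build_chain(sp)$points
    s <- compute_series(pts, protein_id = "x")
    worst_t <- max(worst_t, max(abs(s$angle_deg - sp$torsions)))
    d <- sqrt(rowSums(diff(pts)^2))
    worst_d <- max(worst_d, max(abs(d - sp$segment_lengths)))
    for (i in seq_len(nrow(pts) - 2L)) {
      u <- pts[i, ] - pts[i + 1L, ]; v <- pts[i + 2L, ] - pts[i + 1L, ]
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      worst_a <- max(worst_a, abs(ang - sp$planar_angles[i]))
    }
  }
  expect_lt(worst_t, 1e-6)
  expect_lt(worst_d, 1e-9)
  expect_lt(worst_a, 1e-6)
})

test_that("invalid bundle specs are rejected", {
  expect_error(bundle_spec(3, rep(10, 5), c(90, 0, 90, 90), c(0, 0, 0)),
               "strictly between")
  expect_error(bundle_spec(3, rep(10, 5), c(90, 180, 90, 90), c(0, 0, 0)),
               "strictly between")
  expect_error(bundle_spec(3, rep(10, 4), rep(90, 4), c(0, 0, 0)), "segment")
  expect_error(bundle_spec(3, rep(10, 5), rep(90, 4), c(0, -180, 0)),
               "-180, 180")
})

test_that("the written bundle PDB has the expected structural accounting", {
  sp <- random_spec(3, id = "ACC")
  out <- write_bundle_pdb(build_chain(sp), residues_per_helix = 20)
  expect_equal(sum(startsWith(out$pdb, "HELIX ")), 3L)
  n_atoms <- sum(startsWith(out$pdb, "ATOM "))
  expect_gte(n_atoms, 60L)  # 60 helix residues plus interpolated loops
  expect_equal(nrow(out$annotation), 3L)
  expect_equal(out$annotation$end_residue - out$annotation$start_residue,
               rep(19L, 3))
})

test_that("bundle PDBs survive the full extraction pipeline within 5 degrees", {
  set.seed(77)
  for (r in 1:5) {
    sp <- random_spec(sample(3:6, 1), id = "E2E")
    tf <- withr::local_tempfile(fileext = ".pdb")
    out <- write_bundle_pdb(build_chain(sp), residues_per_helix = 18,
                            file = tf)
    tr <- read_calpha_coordinates(tf, "A")
    topo <- protein_topology(sp$protein_id, "A",
                             out$annotation$start_residue,
                             out$annotation$end_residue)
    got <- compute_series(extract_joints(tr, topo))$angle_deg
    expect_lt(max(ang_diff(got, sp$torsions)), 5)
  }
})

test_that("HELIX records in the written file match the annotation table", {
  sp <- random_spec(4, id = "HR")
  out <- write_bundle_pdb(build_chain(sp), residues_per_helix = 12)
  seg <- read_helix_records(paste(out$pdb, collapse = "\n"), "A")
  expect_equal(seg$start_residue, out$annotation$start_residue)
  expect_equal(seg$end_residue, out$annotation$end_residue)
})

test_that("mirroring the bundle negates every recovered angle", {
  sp <- random_spec(4, id = "MIR")
  js <- build_chain(sp)
  tf <- withr::local_tempfile(fileext = ".pdb")
  out <- write_bundle_pdb(mirror_joints(js, "MIR"), residues_per_helix = 16,
                          file = tf)
  tr <- read_calpha_coordinates(tf, "A")
  topo <- protein_topology("MIR", "A", out$annotation$start_residue,
                           out$annotation$end_residue)
  got <- compute_series(extract_joints(tr, topo))$angle_deg
  expect_lt(max(ang_diff(got, -sp$torsions)), 5)
})

test_that("cohort generation is deterministic and honours its angle model", {
  c1 <- generate_cohort(50, tm_range = c(3, 6), seed = 99)
  c2 <- generate_cohort(50, tm_range = c(3, 6), seed = 99)
  expect_identical(c1, c2)
  ns <- vapply(c1, `[[`, 0L, "n_helices")
  expect_true(all(ns >= 3 & ns <= 6))
  om <- unlist(lapply(c1, function(sp)
    sp$torsions[seq_along(sp$torsions) %% 2 == 1]))
  expect_gt(mean(abs(om) <= 40), 0.9)  # generator contract for the omega band
  expect_true(all(abs(om) >= 10 & abs(om) <= 40))
})

test_that("forcing all lambda angles negative yields pure (-A,-A) dyads", {
  specs <- lapply(1:4, function(i) {
    n <- 5L
    tor <- numeric(2 * n - 3)
    tor[seq_along(tor) %% 2 == 1] <- 20
    tor[seq_along(tor) %% 2 == 0] <- -45
    bundle_spec(n, rep(c(28, 11), length.out = 2 * n - 1),
                rep(85, 2 * n - 2), tor, protein_id = sprintf("L%d", i))
  })
  series <- lapply(specs, function(sp) compute_series(build_chain(sp)))
  pc <- count_patterns(series, kind = "lambda", k = 2, alphabet = "quadrant")
  expect_equal(sum(pc$counts), pc$counts[["-A,-A"]])
  expect_equal(sum(pc$counts > 0), 1L)
  expect_length(pc$counts, 16L)
})
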