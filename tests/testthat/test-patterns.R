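test_that("sign categorisation follows the boundary rule", {
  expect_equal(sign_of(23.4), "+")
  expect_equal(sign_of(-0.1), "-")
  expect_warning(z <- sign_of(0), "boundary")
  expect_equal(z, "+")
  expect_equal(sign_of(c(180, -179.9)), c("+", "-"))
  expect_error(sign_of(-180), "-180, 180")
})

test_that("quadrant categorisation covers the circle with closed outer edges", {
  expect_equal(classify_quadrant(c(45, 135, -45, -135)),
               c("A", "B", "-A", "-B"))
  expect_equal(classify_quadrant(90), "A")
  expect_equal(classify_quadrant(180), "B")
  expect_equal(classify_quadrant(-90), "-A")
  expect_warning(z <- classify_quadrant(0), "boundary")
  expect_equal(z, "A")
})

test_that("sign and quadrant categories are mutually consistent", {
  set.seed(5)
  a <- runif(500, -179.99, 180)
  expect_equal(sign_of(a) == "+", classify_quadrant(a) %in% c("A", "B"))
})

test_that("window enumeration is adjacent-only and ordered", {
  expect_equal(consecutive_patterns(c("+", "+", "-"), 2), c("+,+", "+,-"))
  expect_equal(consecutive_patterns(c("+", "-"), 3), character(0))
  expect_equal(consecutive_patterns(rep("-", 4), 3), c("-,-,-", "-,-,-"))
  expect_error(consecutive_patterns(c("+", "-"), 4), "2 or 3")
})

test_that("pattern counting pools proteins and zero-fills the space", {
  s1 <- series_from_angles(c(10, 50, 20))     # omega signs (+,+)
  s2 <- series_from_angles(c(15, -60, -25))   # omega signs (+,-)
  pc <- count_patterns(list(s1, s2), kind = "omega", k = 2)
  expect_equal(unname(pc$counts[c("+,+", "+,-", "-,+", "-,-")]),
               c(1L, 1L, 0L, 0L))
  expect_length(pc$counts, 4L)
  # lambda quadrant dyads: one protein with three -A lambdas -> 2 windows
  s3 <- series_from_angles(c(10, -45, 20, -30, 15, -60, 25))  # n = 5
  pcq <- count_patterns(list(s3), kind = "lambda", k = 2, alphabet = "quadrant")
  expect_length(pcq$counts, 16L)
  expect_equal(unname(pcq$counts[["-A,-A"]]), 2L)
  expect_equal(sum(pcq$counts), 2L)
})

test_that("quadrant counting is refused for omega angles", {
  s <- series_from_angles(c(10, 50, 20))
  expect_error(count_patterns(list(s), kind = "omega", alphabet = "quadrant"),
               "lambda angles only")
})

test_that("TM-size grouping counts only each group's members", {
  small <- compute_series(build_chain(random_spec(4, id = "S4")))
  large <- compute_series(build_chain(random_spec(12, id = "L12")))
  by_grp <- count_patterns(list(small, large), kind = "omega", k = 2,
                           groups = tm_size_groups())
  expect_named(by_grp, c("3-6 TM", "7-10 TM", "11-14 TM"))
  expect_equal(sum(by_grp[["3-6 TM"]]$counts), 2L)    # 3 omegas -> 2 dyads
  expect_equal(sum(by_grp[["7-10 TM"]]$counts), 0L)
  expect_equal(sum(by_grp[["11-14 TM"]]$counts), 10L) # 11 omegas -> 10 dyads
})

test_that("window counts are conserved across random cohorts", {
  set.seed(123)
  for (rep in 1:5) {
    cohort <- lapply(generate_cohort(8, tm_range = c(3, 9),
                                     seed = 1000 + rep),
                     function(sp) compute_series(build_chain(sp)))
    for (k in 2:3) for (kind in c("omega", "lambda")) {
      pc <- count_patterns(cohort, kind = kind, k = k)
      lens <- vapply(cohort, function(s) sum(s$kind == kind), integer(1))
      expect_equal(sum(pc$counts), sum(pmax(lens - k + 1L, 0L)))
    }
  }
})

test_that("bootstrap SDs are deterministic, zero for degenerate input", {
  obs <- rep("+,+", 10)
  sds <- bootstrap_sd(obs, patterns = c("+,+", "+,-", "-,+", "-,-"),
                      B = 100, seed = 4)
  expect_equal(unname(sds), rep(0, 4))  # constant resamples and never-seen patterns
  obs2 <- c(rep("+,+", 5), rep("-,-", 3))
  s1 <- bootstrap_sd(obs2, B = 200, seed = 7)
  s2 <- bootstrap_sd(obs2, B = 200, seed = 7)
  expect_identical(s1, s2)
  expect_error(bootstrap_sd(character(0)), "no observations")
})

test_that("bootstrap SD matches the binomial closed form", {
  # two windows, one of each pattern: count[(+,+)] ~ Binomial(2, 0.5),
  # SD = sqrt(2 * 0.25) = 0.7071
  sds <- bootstrap_sd(c("+,+", "-,-"), B = 500, seed = 12)
  expect_lt(abs(sds[["+,+"]] - sqrt(0.5)) / sqrt(0.5), 0.10)
  expect_lt(abs(sds[["-,-"]] - sqrt(0.5)) / sqrt(0.5), 0.10)
})

test_that("distribution summaries pair, bin and query correctly", {
  s <- series_from_angles(c(-20, 100, 20))  # one 3-helix protein
  d <- angle_distributions(list(s))
  expect_equal(nrow(d$scatter), 1L)         # omega_1 pairs with lambda_1 only
  expect_equal(d$scatter$omega_deg, -20)
  expect_equal(d$scatter$lambda_deg, 100)
  expect_equal(d$omega_fraction_in_range, 1)  # both omegas inside [-40, 40]
  expect_equal(sum(d$histogram$count[d$histogram$kind == "omega"]), 2L)
  hit <- d$histogram[d$histogram$kind == "lambda" & d$histogram$count > 0, ]
  expect_equal(hit$bin_low, 80)  # 100 falls in (80, 100] with 20-degree bins
  expect_error(angle_distributions(list(s), bin_width = 25), "divide 360")
})

test_that("a generator-controlled cohort shows the bimodal omega histogram", {
  cohort <- lapply(generate_cohort(40, tm_range = c(3, 6), seed = 2024),
                   function(sp) compute_series(build_chain(sp)))
  d <- angle_distributions(cohort)
  om <- d$histogram[d$histogram$kind == "omega", ]
  outside <- om$count[om$bin_low >= 40 | om$bin_high <= -40]
  expect_equal(sum(outside), 0L)           # empty bins outside the +/-40 band
  expect_gt(d$omega_fraction_in_range, 0.9)
  # symmetric bimodality: both signed lobes populated
  expect_gt(sum(om$count[om$bin_high <= 0]), 0)
  expect_gt(sum(om$count[om$bin_low >= 0]), 0)
})
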