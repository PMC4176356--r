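# Scenario generators: the three studied systems, unit conversions and
# the Markov telegraph validation generator.

test_that("the plasmid scenario places sites 180 degrees apart and carries
           its linking deficit", {
  sc <- make_plasmid(-15, 10)
  expect_identical(unname(sc$system$sites), c(1L, 171L))
  expect_identical(abs(diff(unname(sc$system$sites))), 170L)
  expect_equal(sc$system$bp_per_bead * n_beads(sc$system), 3000)
  # Tw + Wr bookkeeping recovers the imposed deficit on frame 0
  expect_lt(abs(linking_number(sc$system) - (-15)), 0.05)
  expect_true(validate_system(sc$system, sc$ff))
  expect_equal(sc$ff$k_dihedral, 65)
  expect_equal(sc$system$affinity_pairs$epsilon, 10)

  relaxed <- make_plasmid(0, 0)
  expect_lt(abs(writhe(relaxed$system)), 1e-10)
  expect_lt(abs(twist(relaxed$system)), 1e-10)
  expect_error(make_plasmid(-25, 0), "outside the studied range")
})

test_that("supercoiled starts are plectonemic and topology-exact for both
           parameterizations", {
  for (dLk in c(-10, 20)) {
    sc <- make_chromatin_loop(dLk, 8)
    expect_lt(abs(linking_number(sc$system) - dLk), 0.05)
    # most of the deficit is already in writhe in the prepared state
    expect_gt(abs(writhe(sc$system)) / abs(dLk), 0.3)
    expect_true(validate_system(sc$system, sc$ff))
  }
})

test_that("the crowded box hits its target volume fraction with intra-loop
           affinity only", {
  sc <- make_crowded_loops(n_copies = 20, dLk = -20, epsilon = 8, seed = 7)
  sys <- sc$system
  # edge = (4000 * pi/6 / 0.2)^(1/3) ~ 21.9 d
  expect_equal(sys$box, (20 * 200 * (pi / 6) / 0.2)^(1 / 3), tolerance = 1e-12)
  expect_equal(sys$box, 21.9, tolerance = 0.005)
  expect_equal(bead_volume_fraction(sys), 0.2, tolerance = 0.01)
  expect_identical(nrow(sys$rings), 20L)
  expect_true(validate_system(sys, sc$ff))
  # every loop keeps its imposed deficit
  expect_lt(max(abs(linking_number(sys) - (-20))), 0.05)
  # affinity pairs never bridge two loops
  loop_of <- function(i) (i - 1L) %/% 200L
  expect_true(all(loop_of(sys$affinity_pairs$a) ==
                    loop_of(sys$affinity_pairs$b)))
  # 100-bead separation corresponds to 400 kb at 4000 bp per bead
  expect_identical(unname(sys$sites[["P1"]] - sys$sites[["E1"]]), 100L)

  dilute <- make_crowded_loops(n_copies = 1, dLk = 0, epsilon = 0, seed = 3)
  expect_identical(nrow(dilute$system$rings), 1L)
})

test_that("tethered domains give E equal contour distance to both promoters", {
  sc <- make_tethered_pair(dLk = 0, epsilon = 8, seed = 2)
  sys <- sc$system
  s <- sys$sites
  # intra-domain distance E-P1 along loop 1
  d_intra <- min(abs(s[["P1"]] - s[["E"]]), 200 - abs(s[["P1"]] - s[["E"]]))
  # inter-domain distance: E to tether bead, one tether bond, then to P2
  d_inter <- abs(s[["E"]] - s[["T1"]]) + 1 + abs(s[["P2"]] - s[["T2"]])
  expect_identical(as.integer(d_intra), as.integer(d_inter))
  # both pairs carry the same affinity
  expect_equal(sys$affinity_pairs$epsilon, c(8, 8))
  expect_identical(sort(sys$affinity_pairs$b),
                   sort(unname(s[c("P1", "P2")])))
  expect_identical(nrow(sys$extra_bonds), 1L)
  expect_true(validate_system(sys, sc$ff))

  sc2 <- make_tethered_pair(dLk = -20, epsilon = 8, seed = 2)
  expect_lt(max(abs(linking_number(sc2$system) - (-20))), 0.05)
})

test_that("the separation sweep maps genomic distances to bead offsets", {
  sweep <- make_separation_sweep(dLk = 0, epsilon = 8)
  expect_named(sweep, c("s16000", "s200000", "s400000"), ignore.order = TRUE)
  seps <- vapply(sweep, function(sc)
    diff(unname(sc$system$sites[c("E", "P")])), numeric(1))
  expect_identical(as.integer(unname(seps[c("s16000", "s200000",
                                            "s400000")])),
                   c(4L, 50L, 100L))
  expect_error(make_separation_sweep(0, 8, separations_bp = 500000),
               "shorter arc")
})

test_that("bead/bp and energy unit conversions match their closed forms", {
  expect_identical(bp_to_beads(800000, 4000), 200L)
  expect_identical(bp_to_beads(16000, 4000), 4L)
  expect_identical(bp_to_beads(0, 4000), 0L)
  # 10 kT at 300 K is about 6 kcal/mol
  expect_equal(kbt_to_kcal(10), 5.96, tolerance = 0.01)
  expect_equal(round(kbt_to_kcal(10)), 6)
})

test_that("the Markov telegraph generator has exponential dwell times and
           the right stationary state", {
  sym <- make_markov_telegraph(0.5, 0.5, 40000, sample_dt = 0.1, seed = 5)
  st <- dwell_stats(sym, B = 100)
  se <- st$ci$se[st$ci$statistic == "fraction_on"]
  expect_lt(abs(st$fraction_on - 0.5), 3 * se)

  # interior on-dwells of a finely sampled telegraph are exponential
  # (lattice deconvolved with half-interval jitter before the KS test)
  sig <- make_markov_telegraph(0.2, 0.1, 3e5, sample_dt = 0.05, seed = 6)
  r <- rle(sig$on)
  k <- length(r$lengths)
  dwell_on <- r$lengths[seq.int(2, k - 1)][r$values[seq.int(2, k - 1)]] * 0.05
  expect_gt(length(dwell_on), 1e4)
  set.seed(1)
  dwell_jit <- dwell_on + runif(length(dwell_on), -0.025, 0.025)
  ks <- suppressWarnings(stats::ks.test(dwell_jit, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)

  expect_identical(nrow(make_markov_telegraph(1, 1, 0, 0.5)), 0L)
})

test_that("build_scenario dispatches on the configuration kind", {
  sc <- build_scenario(list(kind = "plasmid", dLk = -5, epsilon = 10,
                            seed = 3, n_beads = 60))
  expect_identical(sc$config$kind, "plasmid")
  expect_identical(n_beads(sc$system), 60L)
  one <- build_scenario(list(kind = "separation_sweep", dLk = 0, epsilon = 8,
                             separation_bp = 16000))
  expect_s3_class(one, "bd_scenario")
  expect_error(build_scenario(list(kind = "nope")), "unknown scenario")
})
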