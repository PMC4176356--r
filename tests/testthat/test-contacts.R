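# Telegraph signals, dwell statistics, fold-change indices and the
# phase-diagram interpolation.

fake_traj <- function(dists, dt = 1, diameter_nm = 3) {
  nd <- length(dists)
  structure(list(
    times = (seq_len(nd) - 1) * dt,
    wr = matrix(0, nd, 1), tw = matrix(0, nd, 1), rg = rep(1, nd),
    dists = matrix(dists, ncol = 1, dimnames = list(NULL, "d_E.P")),
    snapshots = NULL,
    final = circular_chain(6, sites = c(E = 1L, P = 4L)),
    meta = list(dt = dt, sample_every = 1, box = Inf,
                sites = c(E = 1L, P = 4L),
                track_pairs = matrix(c(1L, 4L), 1),
                bead_diameter_nm = diameter_nm,
                rings = cbind(start = 1L, n = 6L, closed = 1L))),
    class = "bd_trajectory")
}

test_that("the contact criterion is centre distance below two bead diameters", {
  # 5.9 nm and 6.1 nm centre distances for 3 nm beads straddle the
  # threshold; coincident sites are in contact
  d_in_beads <- c(5.9 / 3, 6.1 / 3, 0, 2)
  sig <- telegraph(fake_traj(d_in_beads), "E", "P", threshold = 2)
  expect_identical(sig$on, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(telegraph(fake_traj(1), "E", "Q"), "unknown site")
})

test_that("dwell statistics match hand enumeration with censored boundaries", {
  sig <- telegraph_signal(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                            TRUE), dt_sample = 1)
  st <- dwell_stats(sig, B = 0)
  expect_equal(st$fraction_on, 5 / 8)
  # only the interior off-run of length 3 is uncensored
  expect_equal(st$mean_t_off, 3)
  expect_identical(st$n_off_events, 1L)
  expect_true(is.na(st$mean_t_on))
  expect_identical(st$n_on_events, 0L)

  all_on <- dwell_stats(telegraph_signal(rep(TRUE, 20)), B = 0)
  expect_equal(all_on$fraction_on, 1)
  expect_true(is.na(all_on$mean_t_off))

  td <- tidy(dwell_stats(sig, B = 50))
  expect_true(all(c("statistic", "value", "ci_lo", "ci_hi") %in% names(td)))
})

test_that("dwell estimators recover two-state Markov closed forms", {
  sig <- make_markov_telegraph(k_on = 0.2, k_off = 0.1, duration = 6e4,
                               sample_dt = 0.5, seed = 4)
  st <- dwell_stats(sig, B = 100)
  # stationary fraction-on k_on / (k_on + k_off) = 2/3 within 3 SE
  se_f <- st$ci$se[st$ci$statistic == "fraction_on"]
  expect_lt(abs(st$fraction_on - 2 / 3), 3 * se_f)
  # mean on-dwell 1 / k_off = 10 within 3 SE (plus sampling resolution)
  se_on <- st$ci$se[st$ci$statistic == "mean_t_on"]
  expect_lt(abs(st$mean_t_on - 10), 3 * se_on + 0.5)
})

test_that("fraction-on estimator bias is below 2 percent at 1e4 events", {
  for (rates in list(c(0.2, 0.1), c(0.05, 0.05), c(0.4, 0.1))) {
    k_on <- rates[1]
    k_off <- rates[2]
    duration <- 1e4 * (1 / k_on + 1 / k_off) / 2
    sig <- make_markov_telegraph(k_on, k_off, duration,
                                 sample_dt = 0.2 / max(rates),
                                 seed = round(1000 * k_on + 7))
    st <- dwell_stats(sig, B = 0)
    target <- k_on / (k_on + k_off)
    expect_lt(abs(st$fraction_on - target) / target, 0.02)
  }
})

test_that("fraction-on is invariant under time reversal and stable under
           subsampling", {
  sig <- make_markov_telegraph(0.3, 0.2, 2000, sample_dt = 0.5, seed = 11)
  st <- dwell_stats(sig, B = 0)
  rev_sig <- telegraph_signal(rev(sig$on), 0.5)
  expect_identical(dwell_stats(rev_sig, B = 0)$fraction_on, st$fraction_on)
  # subsampling by 2: exact when runs have even length and even phase,
  # and bounded by one boundary sample per run in general
  runs <- rep(c(TRUE, FALSE), 10)
  det <- telegraph_signal(rep(runs, times = 1, each = 40))
  det_sub <- telegraph_signal(det$on[seq(1, nrow(det), by = 2)], 2)
  expect_equal(dwell_stats(det_sub, B = 0)$fraction_on,
               dwell_stats(det, B = 0)$fraction_on, tolerance = 1e-12)
  sub <- telegraph_signal(sig$on[seq(1, nrow(sig), by = 2)], 1)
  n_sub <- nrow(sub)
  n_runs <- length(rle(sig$on)$lengths)
  expect_lte(abs(dwell_stats(sub, B = 0)$fraction_on - st$fraction_on),
             n_runs / (2 * n_sub))
})

fake_stats <- function(fraction, se = 0.01) {
  structure(list(fraction_on = fraction,
                 dt_sample = 1, total_time = 1000,
                 ci = tibble::tibble(statistic = "fraction_on",
                                     ci_lo = fraction - 2 * se,
                                     ci_hi = fraction + 2 * se, se = se)),
            class = "dwell_stats")
}

test_that("enhancement index is the fold change of fraction-on", {
  same <- enhancement_index(fake_stats(0.4), fake_stats(0.4))
  expect_equal(same$value, 1)
  expect_equal(enhancement_index(fake_stats(0.6), fake_stats(0.2))$value, 3)
  ei <- enhancement_index(fake_stats(0.6), fake_stats(0.2))
  expect_true(ei$ci_lo < 3 && ei$ci_hi > 3)
  und <- enhancement_index(fake_stats(0.5), fake_stats(0))
  expect_true(is.na(und$value))
})

test_that("preference ratio reports intra over inter with a CI floor at
           zero denominator", {
  expect_equal(preference_ratio(fake_stats(0.3), fake_stats(0.3))$value, 1)
  expect_equal(preference_ratio(fake_stats(0.40), fake_stats(0.02))$value, 20)
  lb <- preference_ratio(fake_stats(0.4), fake_stats(0, se = 0.001))
  expect_true(lb$lower_bound)
  expect_gt(lb$value, 1)
})

test_that("phase diagram interpolates an analytic surface and extracts its
           level sets", {
  grid <- expand.grid(dLk = seq(0, 1, length.out = 6),
                      epsilon = seq(0, 1, length.out = 6))
  grid$fraction_on <- grid$dLk * grid$epsilon
  pd <- phase_diagram(grid, levels = c(0.1, 0.25, 0.5, 0.75), n_fine = 101)
  # isolines of f(x, y) = x y are the hyperbolas x y = level
  for (lv in unique(pd$isolines$level)) {
    pts <- dplyr::filter(pd$isolines, .data$level == lv)
    expect_lt(max(abs(pts$dLk * pts$epsilon - lv)), 0.02)
  }
  # a monotone surface has ordered, non-crossing isolines
  mean_pos <- tapply(pd$isolines$dLk + pd$isolines$epsilon,
                     pd$isolines$level, mean)
  expect_true(all(diff(mean_pos[order(as.numeric(names(mean_pos)))]) > 0))
})

test_that("a constant surface yields the single degenerate isoline", {
  grid <- expand.grid(dLk = c(0, -5, -10), epsilon = c(0, 4, 8))
  grid$fraction_on <- 0.5
  pd <- phase_diagram(grid, levels = c(0.1, 0.25, 0.5, 0.75))
  expect_identical(unique(pd$isolines$level), 0.5)
  expect_identical(length(unique(pd$isolines$line_id)), 1L)
})

test_that("missing grid cells are masked and isolines clipped", {
  grid <- expand.grid(dLk = seq(0, 1, length.out = 4),
                      epsilon = seq(0, 1, length.out = 4))
  grid$fraction_on <- grid$dLk * grid$epsilon
  grid <- grid[-7, ]
  pd <- phase_diagram(grid)
  expect_true(anyNA(pd$surface$fraction_on))
})
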