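# Integrator: determinism, trivial limits, Einstein/Boltzmann statistics,
# equilibration estimation, topology conservation and PBC consistency.

free_bead <- function() {
  bead_system(matrix(0, 1, 3), rings = cbind(1L, 1L, 0L))
}

test_that("zero forces at zero temperature leave the state unchanged", {
  sys <- free_bead()
  ff <- force_field()
  out <- bd_step(sys, ff, dt = 1e-3, seed = 1, kT = 0)
  expect_identical(out$positions, sys$positions)
})

test_that("identical seeds give bit-identical trajectories", {
  sc <- make_plasmid(-5, 10, n_beads = 60)
  sch <- bd_schedule(2000, sample_every = 200, seed = 77)
  t1 <- bd_run(sc, sch, record_frames = TRUE, burnin = FALSE)
  t2 <- bd_run(sc, sch, record_frames = TRUE, burnin = FALSE)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$wr, t2$wr)
  t3 <- bd_run(sc, bd_schedule(2000, sample_every = 200, seed = 78),
               burnin = FALSE)
  expect_false(identical(t2$wr, t3$wr))
})

test_that("a zero-step run returns only the initial frame", {
  ring <- circular_chain(12)
  traj <- bd_run(ring, bd_schedule(0, sample_every = 100),
                 ff = force_field(k_bend = 3, k_dihedral = 5),
                 record_frames = TRUE, burnin = FALSE)
  expect_length(traj$times, 1)
  expect_equal(traj$snapshots[[1]][, 1:3], unname(ring$positions))
})

test_that("a free bead diffuses by the Einstein relation (MSD = 6 D t)", {
  traj <- bd_run(free_bead(), bd_schedule(6e4, dt = 1e-3, sample_every = 100,
                                          seed = 31),
                 ff = force_field(), record_frames = TRUE, burnin = FALSE)
  pos <- t(vapply(traj$snapshots, function(s) s[1, 1:3], numeric(3)))
  steps2 <- rowSums(diff(pos)^2)       # independent increments, dt = 0.1
  expected <- 6 * 1 * 0.1
  se <- sd(steps2) / sqrt(length(steps2))
  expect_lt(abs(mean(steps2) - expected), 3 * se)
})

test_that("a harmonic bond samples the Boltzmann length distribution", {
  k <- 100
  sys <- bead_system(rbind(c(0, 0, 0), c(1, 0, 0)), rings = cbind(1L, 2L, 0L))
  traj <- bd_run(sys, bd_schedule(1e6, dt = 1e-4, sample_every = 100,
                                  seed = 7),
                 ff = force_field(k_bond = k, k_bend = 0, k_dihedral = 1),
                 record_frames = TRUE, burnin = FALSE)
  r <- vapply(traj$snapshots, function(s) sqrt(sum((s[2, 1:3] - s[1, 1:3])^2)),
              numeric(1))
  # analytic moments of p(r) ~ r^2 exp(-k (r - 1)^2 / 2)
  Z <- integrate(function(x) x^2 * exp(-0.5 * k * (x - 1)^2), 0, Inf)$value
  m1 <- integrate(function(x) x^3 * exp(-0.5 * k * (x - 1)^2), 0, Inf)$value / Z
  m2 <- integrate(function(x) x^4 * exp(-0.5 * k * (x - 1)^2), 0, Inf)$value / Z
  v_expected <- m2 - m1^2
  v_obs <- var(r)
  se <- v_obs * sqrt(2 / length(r))
  expect_lt(abs(v_obs - v_expected), 3 * se + 0.02 * v_expected)
})

test_that("a relaxed ring has zero mean writhe", {
  # achiral ensemble: signed writhe averages to zero; its slow modes make
  # the effective sample size small, so the standard error comes from
  # block means
  ring <- circular_chain(40)
  traj <- bd_run(ring, bd_schedule(2e6, dt = 2e-4, sample_every = 2000,
                                   seed = 14),
                 ff = force_field(k_bend = 5, k_dihedral = 10),
                 burnin = FALSE)
  wr <- traj$wr[-(1:100), 1]
  blocks <- vapply(split(wr, cut(seq_along(wr), 6)), mean, numeric(1))
  se <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(wr)), 3 * se + 0.05)
})

test_that("a bending unit samples the discrete worm-like-chain angle law", {
  kb <- 3
  sys <- bead_system(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                     rings = cbind(1L, 3L, 0L))
  traj <- bd_run(sys, bd_schedule(4.5e6, dt = 1e-3, sample_every = 750,
                                  seed = 3),
                 ff = force_field(k_bond = 100, k_bend = kb, k_dihedral = 1),
                 record_frames = TRUE, burnin = FALSE)
  beta <- vapply(traj$snapshots, function(s) {
    u <- s[2, 1:3] - s[1, 1:3]
    v <- s[3, 1:3] - s[2, 1:3]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }, numeric(1))
  beta <- beta[-seq_len(100)]
  # closed-form CDF of p(beta) ~ sin(beta) exp(-kb (1 - cos beta))
  cdf <- function(b) (1 - exp(-kb * (1 - cos(b)))) / (1 - exp(-2 * kb))
  ks <- suppressWarnings(stats::ks.test(beta, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("equilibration time estimates match closed forms", {
  set.seed(8)
  tau_wn <- estimate_equilibration(rnorm(5000), dt_sample = 1)
  expect_lt(tau_wn, 1.2)
  expect_true(attr(tau_wn, "converged"))

  rho <- 0.8
  x <- as.numeric(arima.sim(list(ar = rho), 40000))
  tau_ar <- estimate_equilibration(x, dt_sample = 1)
  expect_equal(as.numeric(tau_ar), (1 + rho) / (1 - rho) / 2, tolerance = 0.2)

  expect_warning(tau_c <- estimate_equilibration(rep(1, 500)), "constant")
  expect_false(attr(tau_c, "converged"))
  # a series whose correlation time approaches the window length is
  # flagged as unequilibrated
  set.seed(5)
  slow <- as.numeric(arima.sim(list(ar = 0.995), 300))
  expect_warning(tau_slow <- estimate_equilibration(slow), "unequilibrated")
  expect_false(attr(tau_slow, "converged"))
})

test_that("topology (Lk = Tw + Wr) is conserved along a supercoiled run", {
  sc <- make_plasmid(-4, 0, n_beads = 60)
  traj <- bd_run(sc, bd_schedule(2e5, dt = 1e-4, sample_every = 1000,
                                 seed = 17), burnin = FALSE)
  lk <- traj$wr[, 1] + traj$tw[, 1]
  expect_lt(max(abs(lk - (-4))), 0.05)
})

test_that("energies are invariant under a box-edge shift and the neighbor
           list reproduces the all-pairs dynamics", {
  set.seed(2)
  ring <- circular_chain(20)
  sys <- bead_system(ring$positions, box = 12)
  ff <- force_field(k_bend = 4, k_dihedral = 8)
  e0 <- total_energy(sys, ff)$total
  sh <- sys
  sh$positions <- sweep(sys$positions, 2, c(12, -12, 24), `+`)
  expect_lt(abs(total_energy(sh, ff)$total - e0), 1e-9)

  sch <- bd_schedule(50, dt = 1e-4, sample_every = 50, seed = 4, kT = 0)
  a <- bd_run(sys, sch, ff = ff, burnin = FALSE, use_neighbor_list = TRUE)
  b <- bd_run(sys, sch, ff = ff, burnin = FALSE, use_neighbor_list = FALSE)
  expect_identical(a$final$positions, b$final$positions)
})

test_that("burn-in discards the pre-equilibration stretch", {
  sc <- make_plasmid(-4, 0, n_beads = 60)
  sch <- bd_schedule(3e5, dt = 1e-4, sample_every = 500, seed = 19)
  full <- bd_run(sc, sch, burnin = FALSE)
  trimmed <- bd_run(sc, sch, burnin = TRUE)
  expect_lt(length(trimmed$times), length(full$times))
  expect_gt(trimmed$meta$n_discarded, 0)
  expect_equal(trimmed$meta$equilibration$observable, "writhe")
})
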