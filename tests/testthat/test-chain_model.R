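# Polymer model: potentials, dihedral measurement, energy decomposition
# and analytic gradients.

test_that("torsion potential has the right minimum, maximum and period", {
  expect_equal(torsion_energy(0.3, 65, phi0 = 0.3), 0)
  expect_equal(torsion_energy(pi, 65), 65)
  expect_equal(torsion_energy(pi / 2, 50), 25)
  phi <- seq(-3, 3, length.out = 25)
  expect_equal(torsion_energy(phi + 2 * pi, 17), torsion_energy(phi, 17))
})

test_that("affinity well is a truncated 12-6 Lennard-Jones", {
  expect_equal(affinity_energy(2^(1 / 6), 10), -10)
  expect_equal(affinity_energy(2.0, 12, r_cut = 2), 0)
  expect_equal(affinity_energy(5, 12, r_cut = 2), 0)
  # hand-evaluated 12-6 at r = 1.5 d, eps = 8
  expect_equal(affinity_energy(1.5, 8), 4 * 8 * ((1 / 1.5)^12 - (1 / 1.5)^6),
               tolerance = 1e-12)
  expect_equal(affinity_energy(1.5, 8), -2.56269, tolerance = 1e-4)
  expect_error(affinity_energy(0, 8), "positive")
})

test_that("dihedral angle measures material twist and survives sharp bends", {
  # closed square ring with 90 degree bends: all angles finite
  sq <- bead_system(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                    rings = cbind(1L, 4L, 1L), twist = 0)
  phis <- twist_angles(sq)
  expect_true(all(is.finite(phis)))
  expect_equal(max(abs(phis[-1])), 0, tolerance = 1e-12)

  # collinear interior junction of a closed chain: rectangle long edge
  rect <- bead_system(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
                            c(3, 1, 0), c(2, 1, 0), c(1, 1, 0), c(0, 1, 0)),
                      twist = 0)
  expect_equal(dihedral_angle(rect, 3), 0, tolerance = 1e-12)
})

test_that("dihedral angle agrees with a quaternion frame-transport oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(8:16, 1)
    pos <- random_fourier_loop(n)
    sys <- bead_system(pos, twist = runif(1, -0.4, 0.4))
    v <- sample(n, 3)
    expect_equal(vapply(v, function(j) dihedral_angle(sys, j), numeric(1)),
                 vapply(v, function(j) oracle_dihedral(sys, j), numeric(1)),
                 tolerance = 1e-6)
  }
})

test_that("relaxed circle has vanishing bond, torsion and affinity energy", {
  ring <- circular_chain(24, dLk = 0)
  ff <- force_field(k_bend = 5, k_dihedral = 10, epsilon = 0)
  e <- total_energy(ring, ff)
  expect_lt(abs(e$bond), 1e-20)
  expect_lt(abs(e$torsion), 1e-12)
  expect_identical(e$affinity, 0)
  expect_equal(e$total, e$bond + e$bend + e$torsion + e$excluded_volume +
                 e$affinity, tolerance = 1e-9)
})

test_that("affinity is zero for sites farther apart than the cutoff", {
  ring <- circular_chain(30, sites = c(E = 1L, P = 16L),
                         affinity_pairs = data.frame(a = 1L, b = 16L,
                                                     epsilon = 10))
  ff <- force_field(k_bend = 5, k_dihedral = 10, epsilon = 10)
  # diametrically opposite on a 30-bead ring: far beyond r_cut = 2 d
  expect_identical(total_energy(ring, ff)$affinity, 0)
})

test_that("total energy matches a brute-force summation oracle on an 8-bead ring", {
  set.seed(11)
  pos <- random_fourier_loop(8)
  sys <- bead_system(pos, twist = 0.3,
                     affinity_pairs = data.frame(a = 1L, b = 4L, epsilon = 5))
  ff <- force_field(k_bond = 80, k_bend = 4, k_dihedral = 12, epsilon = 5)
  e <- total_energy(sys, ff)
  o <- oracle_energy(sys, ff)
  for (term in c("bond", "bend", "torsion", "excluded_volume", "affinity",
                 "total"))
    expect_equal(e[[term]], o[[term]], tolerance = 1e-9, info = term)
})

test_that("analytic forces and torques match finite differences of the energy", {
  set.seed(99)
  worst_f <- 0
  worst_t <- 0
  for (rep in 1:100) {
    n <- sample(8:20, 1)
    pos <- random_fourier_loop(n)
    sys <- bead_system(pos, twist = runif(1, -0.5, 0.5),
                       affinity_pairs = data.frame(
                         a = 1L, b = sample(3:(n - 2), 1), epsilon = 6))
    ff <- force_field(k_bond = 60, k_bend = 6, k_dihedral = 25, epsilon = 6)
    an <- forces_and_torques(sys, ff)
    fd <- oracle_fd_forces(sys, ff)
    scale_f <- max(abs(fd), 1)
    worst_f <- max(worst_f, max(abs(an$forces - fd)) / scale_f)
    if (rep <= 20) {
      td <- oracle_fd_torques(sys, ff)
      worst_t <- max(worst_t, max(abs(an$torques - td)) / max(abs(td), 1))
    }
    # Newton's third law: forces sum to zero
    expect_lt(max(abs(colSums(an$forces))), 1e-9)
  }
  expect_lt(worst_f, 1e-5)
  expect_lt(worst_t, 1e-5)
})

test_that("energy terms are invariant under rigid motions", {
  set.seed(5)
  pos <- random_fourier_loop(14)
  sys <- bead_system(pos, twist = 0.2,
                     affinity_pairs = data.frame(a = 1L, b = 7L, epsilon = 4))
  ff <- force_field(k_bend = 6, k_dihedral = 15, epsilon = 4)
  e0 <- total_energy(sys, ff)
  # translation
  sys_t <- sys
  sys_t$positions <- sweep(sys$positions, 2, c(3.2, -1.1, 0.7), `+`)
  expect_lt(abs(total_energy(sys_t, ff)$total - e0$total), 1e-9)
  # rotation (positions and frames together)
  R <- coilsim:::.rotation_about(c(1, 2, 3), 1.234)
  sys_r <- sys
  sys_r$positions <- sys$positions %*% t(R)
  sys_r$frames <- sys$frames %*% t(R)
  expect_lt(abs(total_energy(sys_r, ff)$total - e0$total), 1e-9)
})

test_that("system validation enforces the chain invariants", {
  expect_error(circular_chain(4), "at least 6")
  ring <- circular_chain(12)
  expect_true(validate_system(ring))
  bad <- ring
  bad$positions[3, ] <- bad$positions[3, ] + c(0.5, 0, 0)
  expect_error(validate_system(bad), "bond lengths")
  expect_error(bead_system(matrix(0, 6, 3), sites = c(E = 2L, P = 2L)),
               "distinct")
  expect_error(bead_system(diag(3) * 5, rings = cbind(1L, 3L, 0L),
                           sites = c(E = 9L)), "range")
})
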