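# Polymer data model and energy terms: bead systems (one or more rings,
# optional tether bonds and affinity pairs), force fields, and the
# individual potentials of the coarse-grained model.

#' Construct a bead system
#'
#' A bead system is the simulation state: bead positions, per-edge material
#' frame vectors (which carry the twist degrees of freedom), the ring
#' partition, labelled special sites (enhancers/promoters), affinity pairs,
#' optional tether bonds, and an optional periodic box.
#'
#' Material twist is represented by a unit frame vector per chain edge,
#' perpendicular to that edge. The twist angle at a junction is the
#' rotation from the parallel-transported frame of the incoming edge to
#' the frame of the outgoing edge; with this convention the discrete
#' Calugareanu identity Lk = Tw + Wr holds exactly for every closed ring,
#' so the imposed linking-number deficit is conserved by the dynamics
#' unless segments cross.
#'
#' @param positions numeric n x 3 matrix of bead centres, in bead diameters.
#' @param rings integer matrix with columns `start`, `n`, `closed`
#'   describing contiguous bead blocks (1-based starts). Defaults to a
#'   single closed ring over all beads.
#' @param twist per-junction twist angles (radians) used to build the
#'   material frames, recycled along each ring; junction i of a ring is
#'   assigned `twist[i]` for i = 2..n and the seam junction angle follows
#'   from ribbon closure. A scalar imposes uniform twist.
#' @param frames optionally, an n x 3 matrix of ready-made frame vectors
#'   (overrides `twist`).
#' @param bead_diameter_nm physical bead diameter (3 for DNA, 30 for
#'   chromatin fibre).
#' @param bp_per_bead base pairs represented by one bead.
#' @param sites named integer vector of special bead indices
#'   (e.g. `c(E = 1, P = 171)`).
#' @param affinity_pairs data frame with columns `a`, `b`, `epsilon`
#'   listing the site pairs that attract (the only pairs the affinity well
#'   applies to).
#' @param extra_bonds data frame with columns `a`, `b`, `k`, `r0` of
#'   additional harmonic bonds (e.g. the tether joining two domains).
#' @param box periodic cubic box edge in bead diameters, or `Inf` for
#'   unbounded (dilute) systems.
#' @return an object of class `bead_system`.
#' @export
bead_system <- function(positions, rings = NULL, twist = 0, frames = NULL,
                        bead_diameter_nm = 3, bp_per_bead = NULL,
                        sites = integer(), affinity_pairs = NULL,
                        extra_bonds = NULL, box = Inf) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("`positions` must be an n x 3 matrix")
  n <- nrow(positions)
  if (is.null(rings)) rings <- cbind(start = 1L, n = n, closed = 1L)
  rings <- matrix(as.integer(rings), ncol = 3,
                  dimnames = list(NULL, c("start", "n", "closed")))
  if (sum(rings[, "n"]) != n) stop("ring blocks must partition the beads")
  if (length(sites)) {
    sites <- setNames(as.integer(sites), names(sites))
    if (anyDuplicated(sites)) stop("special site indices must be distinct")
    if (any(sites < 1L | sites > n)) stop("special site index out of range")
  }
  if (is.null(frames)) {
    tw <- rep(0, n)
    for (r in seq_len(nrow(rings))) {
      idx <- rings[r, "start"] + seq_len(rings[r, "n"]) - 1L
      tw[idx] <- rep_len(twist, rings[r, "n"])
    }
    frames <- cs_build_frames(positions, .rings0(rings), tw)
  }
  sys <- structure(list(
    positions = positions,
    frames = frames,
    rings = rings,
    bead_diameter_nm = bead_diameter_nm,
    bp_per_bead = bp_per_bead,
    sites = sites,
    affinity_pairs = affinity_pairs %||%
      data.frame(a = integer(), b = integer(), epsilon = double()),
    extra_bonds = extra_bonds %||%
      data.frame(a = integer(), b = integer(), k = double(), r0 = double()),
    box = box
  ), class = "bead_system")
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rings0 <- function(rings) {
  out <- rings
  out[, 1] <- out[, 1] - 1L
  out
}

#' Number of beads of a system
#' @param x a `bead_system`
#' @export
n_beads <- function(x) nrow(x$positions)

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf("<bead_system> %d beads in %d ring(s)%s\n", n_beads(x),
              nrow(x$rings),
              if (is.finite(x$box)) sprintf(", periodic box L = %.3g d", x$box)
              else ", unbounded"))
  if (length(x$sites))
    cat("  sites:", paste(sprintf("%s=%d", names(x$sites), x$sites),
                          collapse = ", "), "\n")
  if (nrow(x$affinity_pairs))
    cat(sprintf("  %d affinity pair(s), epsilon = %s kT\n",
                nrow(x$affinity_pairs),
                paste(unique(x$affinity_pairs$epsilon), collapse = "/")))
  invisible(x)
}

#' Closed circular chain
#'
#' Builds a flat circle of `n` beads at unit bond length with a uniform
#' stored twist encoding the imposed linking-number deficit: every
#' junction receives 2 * pi * dLk / n radians of material twist, so on the
#' planar (writhe-free) circle Tw = dLk and Lk = Tw + Wr = dLk.
#'
#' @param n number of beads (>= 6).
#' @param dLk imposed linking-number deficit (turns, integer-valued for a
#'   closable ribbon).
#' @inheritParams bead_system
#' @export
circular_chain <- function(n, dLk = 0, bead_diameter_nm = 3,
                           bp_per_bead = NULL, sites = integer(), ...) {
  if (n < 6) stop("a closed ring needs at least 6 beads")
  radius <- 0.5 / sin(pi / n)
  th <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(radius * cos(th), radius * sin(th), 0)
  bead_system(pos, twist = 2 * pi * dLk / n,
              bead_diameter_nm = bead_diameter_nm, bp_per_bead = bp_per_bead,
              sites = sites, ...)
}

#' Pre-built plectonemic ring
#'
#' Constructs an interwound (plectonemic) closed curve carrying most of
#' the imposed deficit as writhe, with the remainder stored as uniform
#' material twist. Starting runs from this state instead of a twisted
#' flat circle skips the slow buckling transient.
#'
#' The curve is two antiparallel superhelices joined by end caps; the
#' number of interwound turns is chosen so that the measured writhe of
#' the constructed curve is closest to `target_wr` (default 0.8 * dLk).
#'
#' @inheritParams circular_chain
#' @param target_wr writhe aimed for by the geometric construction;
#'   the actual writhe of the returned ring is measured, and the stored
#'   twist is set to `dLk - Wr` so that Lk = dLk exactly.
#' @param align_sites roll the contour parameterization so that the two
#'   labelled sites start as close together as the interwound geometry
#'   allows (on opposing strands). Without this, sites half a contour
#'   apart sit at the two apical loops of the fresh plectoneme, and
#'   bringing them together requires slithering by a quarter contour --
#'   far slower than desk-scale runs. Site labels are unaffected; only
#'   where the interwound sits along the contour changes.
#' @export
plectoneme_chain <- function(n, dLk, bead_diameter_nm = 3, bp_per_bead = NULL,
                             sites = integer(), target_wr = 0.8 * dLk,
                             align_sites = TRUE, ...) {
  if (n < 6) stop("a closed ring needs at least 6 beads")
  if (abs(dLk) < 1) return(circular_chain(n, dLk, bead_diameter_nm,
                                          bp_per_bead, sites, ...))
  sgn <- sign(dLk)
  best <- NULL
  for (m in unique(pmax(2, round(abs(target_wr) * c(0.8, 0.9, 1, 1.1, 1.25))))) {
    pos <- .plectoneme_curve(n, m, handedness = -sgn)
    wr <- cs_writhe(pos, cbind(0L, n, 1L))[1]
    if (is.null(best) || abs(wr - target_wr) < abs(best$wr - target_wr))
      best <- list(pos = pos, wr = wr)
  }
  pos <- best$pos
  if (align_sites && length(sites) >= 2) {
    i <- min(sites[1:2])
    offset <- abs(diff(as.integer(sites[1:2])))
    shifted <- pos[(seq_len(n) - 1L + offset) %% n + 1L, , drop = FALSE]
    k_star <- which.min(rowSums((shifted - pos)^2))
    roll <- (k_star - i) %% n
    if (roll > 0) pos <- pos[c((roll + 1L):n, 1:roll), , drop = FALSE]
  }
  twist_total <- 2 * pi * (dLk - best$wr)
  bead_system(pos, twist = twist_total / n,
              bead_diameter_nm = bead_diameter_nm, bp_per_bead = bp_per_bead,
              sites = sites, ...)
}

# closed interwound curve: two superhelices of m turns joined by caps;
# handedness < 0 gives negative writhe
.plectoneme_curve <- function(n, m, handedness = -1) {
  # superhelix radius limited by the contour available per strand
  r <- min(2, 0.75 * (n / 2) / (2 * pi * m))
  r <- max(r, 0.55)
  n_cap <- max(4L, round(0.05 * n))
  n_hel <- (n - 2L * n_cap) %/% 2L
  helix_turns <- m
  # axial extent from the contour budget of one strand
  arc_xy <- 2 * pi * helix_turns * r
  h <- sqrt(max(n_hel^2 - arc_xy^2, (0.2 * n_hel)^2))
  # interwound pair: at every height the two strands sit half a turn
  # apart; traversed in path order the return strand runs down in z
  s <- seq(0, 1, length.out = n_hel)
  ang_up <- handedness * 2 * pi * helix_turns * s
  up <- cbind(r * cos(ang_up), r * sin(ang_up), h * s)
  ang_dn <- handedness * 2 * pi * helix_turns * rev(s) + pi
  down <- cbind(r * cos(ang_dn), r * sin(ang_dn), h * rev(s))
  # caps: semicircles joining strand ends, bulging axially
  cap <- function(p, q, zdir, nn) {
    mid <- (p + q) / 2
    rad <- sqrt(sum((p - q)^2)) / 2
    u <- (q - p) / sqrt(sum((p - q)^2))
    w <- c(0, 0, zdir)
    th <- seq(pi, 0, length.out = nn + 2)[-c(1, nn + 2)]
    t(sapply(th, function(a) mid - rad * cos(a) * u + rad * sin(a) * w))
  }
  top_cap <- cap(up[n_hel, ], down[1, ], +1, n_cap)
  bot_cap <- cap(down[n_hel, ], up[1, ], -1, n_cap)
  path <- rbind(up, top_cap, down, bot_cap)
  .resample_closed(path, n)
}

# resample a closed polyline to n beads at (approximately) equal spacing
.resample_closed <- function(path, n) {
  closed <- rbind(path, path[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  at <- seq(0, total, length.out = n + 1)[-(n + 1)]
  out <- sapply(1:3, function(k) approx(cum, closed[, k], xout = at)$y)
  # rescale so the mean chord (bond) length is exactly 1
  chords <- sqrt(rowSums((out[c(2:n, 1), ] - out)^2))
  out / mean(chords)
}

#' Equilibrium-sampled open worm-like chain
#'
#' Draws an open bead chain directly from the Boltzmann distribution of
#' the discrete worm-like chain: independent junction bending angles with
#' density proportional to `sin(beta) exp(-k_bend (1 - cos beta))`
#' (inverse-CDF sampling) and uniform azimuths, at unit bond length.
#' Useful as an equilibrated start for persistence-length measurements --
#' the stiff bending modes that take very long to relax from a straight
#' or circular start are already at equilibrium (excluded-volume
#' corrections still need a short dynamics run).
#'
#' @param n number of beads
#' @param k_bend bending stiffness, kT
#' @param seed RNG seed
#' @inheritParams bead_system
#' @export
sampled_wlc_chain <- function(n, k_bend, seed = 1, bead_diameter_nm = 3) {
  set.seed(seed)
  u <- runif(n - 2)
  cosb <- 1 + log(1 - u * (1 - exp(-2 * k_bend))) / k_bend
  azim <- runif(n - 2, 0, 2 * pi)
  tang <- matrix(0, n - 1, 3)
  tang[1, ] <- c(1, 0, 0)
  ref <- c(0, 0, 1)
  for (i in 2:(n - 1)) {
    t0 <- tang[i - 1, ]
    e1 <- ref - sum(ref * t0) * t0
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t0[2] * e1[3] - t0[3] * e1[2], t0[3] * e1[1] - t0[1] * e1[3],
            t0[1] * e1[2] - t0[2] * e1[1])
    sb <- sqrt(max(0, 1 - cosb[i - 1]^2))
    tang[i, ] <- cosb[i - 1] * t0 +
      sb * (cos(azim[i - 1]) * e1 + sin(azim[i - 1]) * e2)
    ref <- e1   # transported reference keeps the frame non-degenerate
  }
  pos <- rbind(c(0, 0, 0), apply(tang, 2, cumsum))
  bead_system(pos, rings = cbind(1L, as.integer(n), 0L),
              bead_diameter_nm = bead_diameter_nm)
}

# --------------------------------------------------------------- force field

#' Force-field parameter set
#'
#' All parameters are in reduced units (lengths in bead diameters d,
#' energies in kT). The model has five terms:
#' harmonic bonds `0.5 k_bond (r - rest_length)^2`; discrete worm-like
#' chain bending `k_bend (1 - cos beta)` with `k_bend` equal to the
#' persistence length in bond lengths (first order); the dihedral twist
#' potential `0.5 k_dihedral (1 - cos(phi - phi0))` acting on the
#' parallel-transport twist angle of each junction; purely repulsive
#' excluded volume (truncated-shifted 12-6 at `2^(1/6) d`, effective
#' diameter d) between all non-bonded bead pairs; and a truncated 12-6
#' Lennard-Jones affinity well of depth `epsilon`, cut at `r_cut`, applied
#' only to designated enhancer-promoter pairs.
#'
#' @param k_bond harmonic bond stiffness (kT / d^2).
#' @param rest_length bond rest length (d).
#' @param k_bend bending stiffness (kT); equals the persistence length in
#'   bond lengths.
#' @param k_dihedral torsional stiffness k of `0.5 k (1 - cos phi)`
#'   (kT; 65 for DNA, 50 for chromatin fibre).
#' @param phi0 equilibrium twist offset per junction (radians). The
#'   default parameterization imposes the linking deficit through the
#'   initial stored twist instead, leaving `phi0 = 0`.
#' @param epsilon affinity well depth (kT, 0 to 12 in the studied range).
#' @param sigma_lj Lennard-Jones sigma of the affinity well (d).
#' @param r_cut affinity cutoff (d); the potential is exactly zero beyond.
#' @param eps_ev,sigma_ev excluded-volume energy scale and diameter.
#' @return object of class `force_field`.
#' @export
force_field <- function(k_bond = 200, rest_length = 1, k_bend = 17,
                        k_dihedral = 65, phi0 = 0, epsilon = 0,
                        sigma_lj = 1, r_cut = 2, eps_ev = 1, sigma_ev = 1) {
  stopifnot(epsilon >= 0, r_cut > sigma_lj, k_dihedral > 0)
  structure(list(k_bond = k_bond, rest_length = rest_length, k_bend = k_bend,
                 k_dihedral = k_dihedral, phi0 = phi0, epsilon = epsilon,
                 sigma_lj = sigma_lj, r_cut = r_cut, eps_ev = eps_ev,
                 sigma_ev = sigma_ev),
            class = "force_field")
}

#' DNA parameterization: 3 nm beads, 51 nm (17 bead) persistence length,
#' torsional stiffness 65 kT.
#' @param epsilon affinity well depth in kT
#' @export
ff_dna <- function(epsilon = 0) {
  force_field(k_bend = 17, k_dihedral = 65, epsilon = epsilon)
}

#' Chromatin-fibre parameterization: 30 nm beads, 60 nm persistence
#' length, high torsional stiffness 50 kT.
#'
#' At two bonds per persistence length the first-order mapping
#' `k_bend = P / l` over-stiffens the fibre: excluded volume between
#' near-neighbour beads suppresses sharp bends and adds its own
#' entropic rigidity. The default bending constant is therefore
#' calibrated (k_bend = 1.4 kT) so that simulated fibres return a 60 nm
#' persistence length from tangent-correlation fits.
#'
#' @param epsilon affinity well depth in kT
#' @param k_dihedral torsional stiffness, adjustable for the writhe
#'   calibration
#' @param k_bend calibrated bending constant
#' @export
ff_chromatin <- function(epsilon = 0, k_dihedral = 50, k_bend = 1.4) {
  force_field(k_bend = k_bend, k_dihedral = k_dihedral, epsilon = epsilon)
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf(paste0("<force_field> k_bond=%g kT/d^2, k_bend=%g kT, ",
                     "k_dihedral=%g kT, epsilon=%g kT (r_cut=%g d)\n"),
              x$k_bond, x$k_bend, x$k_dihedral, x$epsilon, x$r_cut))
  invisible(x)
}

# assemble the flat parameter list the C++ layer expects
.ff_list <- function(sys, ff) {
  ap <- sys$affinity_pairs
  xb <- sys$extra_bonds
  list(k_bond = ff$k_bond, rest_length = ff$rest_length, k_bend = ff$k_bend,
       k_dihedral = ff$k_dihedral, phi0 = ff$phi0, eps_ev = ff$eps_ev,
       sigma_ev = ff$sigma_ev, sigma_lj = ff$sigma_lj, r_cut = ff$r_cut,
       aff_pairs = matrix(as.integer(c(ap$a - 1L, ap$b - 1L)), ncol = 2),
       aff_eps = as.double(ap$epsilon),
       extra_bonds = matrix(as.integer(c(xb$a - 1L, xb$b - 1L)), ncol = 2),
       extra_k = as.double(xb$k), extra_r0 = as.double(xb$r0),
       box = if (is.finite(sys$box)) sys$box else -1)
}

# ------------------------------------------------------------------ energies

#' Dihedral twist angle at a junction
#'
#' Material-frame rotation between consecutive segments, measured after
#' parallel transport of the frame of the incoming edge onto the outgoing
#' tangent. The scheme is exact to first order in the bending angle and
#' remains well defined at 90-degree bends; only antiparallel consecutive
#' tangents (a 180-degree fold) are degenerate.
#'
#' @param chain a `bead_system`
#' @param junction_index vertex index (1-based); the junction sits between
#'   the edge arriving at and the edge leaving this bead.
#' @return angle in (-pi, pi], radians
#' @export
dihedral_angle <- function(chain, junction_index) {
  phis <- cs_phis(chain$positions, chain$frames, .rings0(chain$rings))
  phi <- phis[junction_index]
  if (any(is.na(phi))) stop("no junction at this vertex (open chain end)")
  phi
}

#' Per-junction twist angles of a system
#' @param chain a `bead_system`
#' @return numeric vector, one entry per bead (NA where no junction exists)
#' @export
twist_angles <- function(chain) {
  cs_phis(chain$positions, chain$frames, .rings0(chain$rings))
}

#' Torsional potential
#'
#' `V(phi) = 0.5 k (1 - cos(phi - phi0))`: zero at `phi = phi0`, maximal
#' (`= k`) at a half-turn of twist deviation, and 2*pi periodic.
#'
#' @param phi twist angle(s), radians
#' @param k torsional stiffness, kT
#' @param phi0 equilibrium twist offset, radians
#' @export
torsion_energy <- function(phi, k, phi0 = 0) {
  stopifnot(k > 0)
  0.5 * k * (1 - cos(phi - phi0))
}

#' Truncated Lennard-Jones affinity well
#'
#' Standard 12-6 Lennard-Jones with well depth `epsilon`, truncated at
#' `r_cut` (exactly zero beyond). This term applies only to designated
#' enhancer-promoter bead pairs.
#'
#' @param r centre-to-centre distance(s), d; must be positive
#' @param epsilon well depth, kT
#' @param sigma LJ sigma, d
#' @param r_cut cutoff, d
#' @export
affinity_energy <- function(r, epsilon, sigma = 1, r_cut = 2) {
  if (any(r <= 0)) stop("distance must be positive")
  sr6 <- (sigma / r)^6
  ifelse(r >= r_cut, 0, 4 * epsilon * (sr6^2 - sr6))
}

#' Total energy, decomposed by term
#'
#' @param system a `bead_system`
#' @param ff a `force_field`
#' @return an `energy_breakdown`: bond, bend, torsion, excluded_volume,
#'   affinity and their total (kT)
#' @export
total_energy <- function(system, ff) {
  e <- cs_energy(system$positions, system$frames, .rings0(system$rings),
                 .ff_list(system, ff))
  structure(e, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (kT)\n")
  for (nm in c("bond", "bend", "torsion", "excluded_volume", "affinity",
               "total"))
    cat(sprintf("  %-16s %12.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
tidy.energy_breakdown <- function(x, ...) {
  tibble::tibble(term = c("bond", "bend", "torsion", "excluded_volume",
                          "affinity", "total"),
                 energy = unlist(x[c("bond", "bend", "torsion",
                                     "excluded_volume", "affinity",
                                     "total")], use.names = FALSE))
}

#' Analytic forces and twist torques
#'
#' Negative gradients of [total_energy()]: per-bead force vectors and, for
#' every edge of a closed ring, the generalized torque conjugate to
#' rotating that edge's material frame about its tangent. The positional
#' gradient of the transport twist uses the curvature-binormal formula of
#' discrete rod mechanics, so twist stress feeds back on the geometry
#' (this is what converts stored twist into writhe).
#'
#' @inheritParams total_energy
#' @return list with `forces` (n x 3) and `torques` (length n, per edge)
#' @export
forces_and_torques <- function(system, ff) {
  cs_forces(system$positions, system$frames, .rings0(system$rings),
            .ff_list(system, ff))
}

# ---------------------------------------------------------------- validation

#' Validate chain invariants of a system
#'
#' Checks that the ring partition is consistent, closed rings have at
#' least 6 beads, all bond lengths lie within the valid-dynamics window
#' `[0.8, 1.2]` of the rest length, frames are unit and perpendicular to
#' their edges, and special sites are distinct and in range.
#'
#' @param system a `bead_system`
#' @param ff force field providing the rest length (default 1 d)
#' @return invisibly `TRUE`; errors otherwise
#' @export
validate_system <- function(system, ff = force_field()) {
  pos <- system$positions
  for (r in seq_len(nrow(system$rings))) {
    st <- system$rings[r, "start"]
    n <- system$rings[r, "n"]
    closed <- system$rings[r, "closed"] == 1L
    if (closed && n < 6) stop("closed ring with fewer than 6 beads")
    idx <- st + seq_len(n) - 1L
    nxt <- if (closed) c(idx[-1], idx[1]) else idx[-1]
    cur <- if (closed) idx else idx[-n]
    bl <- sqrt(rowSums((pos[nxt, , drop = FALSE] - pos[cur, , drop = FALSE])^2))
    if (any(bl < 0.8 * ff$rest_length | bl > 1.2 * ff$rest_length))
      stop(sprintf("ring %d: bond lengths outside [0.8, 1.2] of rest length (range %.3f-%.3f)",
                   r, min(bl), max(bl)))
    if (closed) {
      tang <- (pos[nxt, , drop = FALSE] - pos[cur, , drop = FALSE]) / bl
      f <- system$frames[cur, , drop = FALSE]
      if (max(abs(rowSums(f * tang))) > 1e-6)
        stop("frame vectors not perpendicular to their edges")
      if (max(abs(sqrt(rowSums(f^2)) - 1)) > 1e-6)
        stop("frame vectors not unit length")
    }
  }
  if (length(system$sites)) {
    if (anyDuplicated(system$sites)) stop("duplicate special sites")
    if (any(system$sites < 1 | system$sites > n_beads(system)))
      stop("special site out of range")
  }
  invisible(TRUE)
}
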