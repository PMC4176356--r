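# Scenario generators: every initial condition and validation signal the
# analysis needs. Defaults encode the studied systems: a 3 kb plasmid of
# 340 DNA beads with sites 180 degrees apart; 200-bead chromatin loops
# (4000 bp/bead, ~800 kb, the size of a topological domain) singly, in a
# crowded periodic box at 20 % volume fraction, or as two tethered
# domains; and two-state Markov telegraphs for estimator validation.

.PLASMID_BEADS <- 340L      # 3000 bp at 0.34 nm/bp rise over 3 nm beads
.PLASMID_BP <- 3000
.LOOP_BEADS <- 200L
.LOOP_BP_PER_BEAD <- 4000

#' @export
print.bd_scenario <- function(x, ...) {
  cat(sprintf("<bd_scenario> %s: dLk = %g, epsilon = %g kT, seed = %s\n",
              x$config$kind, x$config$dLk %||% 0, x$config$epsilon %||% 0,
              format(x$config$seed)))
  print(x$system)
  invisible(x)
}

.new_scenario <- function(system, ff, config) {
  structure(list(system = system, ff = ff, config = config),
            class = "bd_scenario")
}

# build a supercoiled ring from progressively less writhed plectonemic
# starts until the settled state keeps its imposed topology exactly
.build_supercoiled <- function(n, dLk, ff, bead_diameter_nm, bp_per_bead,
                               sites, aff, fracs = c(0.8, 0.65, 0.5, 0.35),
                               align_sites = TRUE) {
  for (frac in fracs) {
    sys <- plectoneme_chain(n, dLk, bead_diameter_nm = bead_diameter_nm,
                            bp_per_bead = bp_per_bead, sites = sites,
                            affinity_pairs = aff, target_wr = frac * dLk,
                            align_sites = align_sites)
    # settle bonds and contacts with torsion off, then store the twist
    # remainder on the settled geometry so that Lk = dLk exactly
    sys <- .prerelax(sys, ff)
    sys <- .set_twist(sys, dLk)
    lk_ok <- abs(linking_number(sys) - dLk) < 0.05
    valid <- tryCatch({
      validate_system(sys, ff)
      TRUE
    }, error = function(e) FALSE)
    if (lk_ok && valid) return(sys)
  }
  stop(sprintf("could not build a valid supercoiled ring at dLk = %g", dLk))
}

# rebuild the material frames with uniform per-junction twist so that
# every closed ring carries exactly its imposed linking deficit
.set_twist <- function(system, dLk) {
  dLk <- rep_len(dLk, nrow(system$rings))
  wr <- writhe(system)
  tw <- rep(0, n_beads(system))
  for (r in seq_len(nrow(system$rings))) {
    if (system$rings[r, "closed"] != 1L) next
    idx <- system$rings[r, "start"] + seq_len(system$rings[r, "n"]) - 1L
    tw[idx] <- 2 * pi * (dLk[r] - wr[r]) / system$rings[r, "n"]
  }
  system$frames <- cs_build_frames(system$positions, .rings0(system$rings), tw)
  system
}

# pull designated site pairs into the bound state with temporary soft
# harmonic capture bonds, then re-impose the exact topology. Affinity
# scenarios start bound: at desk scale the binding/unbinding alternation
# around the bound state is sampled in minutes, whereas the first
# diffusive encounter of two distant sites is a cluster-scale event.
.capture_sites <- function(system, ff, dLk, pairs = NULL, seed = 1) {
  ap <- pairs %||% system$affinity_pairs
  ap <- ap[ap$epsilon > 0, , drop = FALSE]
  if (!nrow(ap)) return(system)
  sys <- system
  sys$extra_bonds <- rbind(system$extra_bonds,
                           data.frame(a = ap$a, b = ap$b, k = 10, r0 = 1.1))
  # folding a wide ring onto itself is slow collective motion: descend
  # at zero temperature and scale the stage with the initial separation
  d0 <- max(sqrt(rowSums((system$positions[ap$a, , drop = FALSE] -
                            system$positions[ap$b, , drop = FALSE])^2)))
  n_steps <- min(as.integer(30000 + 6000 * d0), 320000L)
  sys <- .prerelax(sys, ff, n_steps = n_steps, dt = 1e-4, max_disp = 0.08,
                   seed = seed)
  # settle at a gentler cap before releasing the capture bond
  sys <- .prerelax(sys, ff, n_steps = 8000, dt = 1e-4, max_disp = 0.03)
  sys$extra_bonds <- system$extra_bonds
  .set_twist(sys, dLk)
}

# short deterministic push-off / settling at zero temperature; torsion is
# switched off here (the twist is re-imposed on the settled geometry by
# .set_twist) so that no torsional driving can force strand passages
.prerelax <- function(system, ff, n_steps = 3000, dt = 5e-5, max_disp = 0.05,
                      kT = 0, seed = 1) {
  ffl <- .ff_list(system, ff)
  ffl$k_dihedral <- 0
  res <- cs_run(system$positions, system$frames, .rings0(system$rings),
                ffl, dt, n_steps, as.integer(n_steps),
                as.double(seed), kT, 1 / 3, FALSE,
                matrix(integer(), ncol = 2), TRUE, FALSE,
                max_disp)
  system$positions <- res$positions
  system$frames <- res$frames
  system
}

#' Supercoiled plasmid scenario
#'
#' A 340-bead DNA ring (3 nm beads, 17-bead persistence length,
#' torsional stiffness 65 kT) representing a 3000 bp plasmid, with
#' enhancer and promoter sites diametrically opposed on the circular map
#' (beads 1 and 171). Supercoiled states start from a pre-built
#' plectonemic conformation carrying the full linking deficit
#' (Lk = Tw + Wr = dLk on the initial frame) with the two sites
#' juxtaposed mid-interwound; relaxed states start from a flat circle.
#' When the pair carries affinity the scenario starts in the bound
#' state (see the methods vignette on desk-scale contact sampling).
#'
#' @param dLk imposed linking-number deficit (|dLk| <= 20)
#' @param epsilon enhancer-promoter affinity well depth, kT
#' @param seed seed recorded in the scenario config (used by the runs)
#' @param n_beads bead count of the ring
#' @param start `"plectoneme"` (default for dLk != 0) or `"circle"`, the
#'   twisted-flat-circle cross-check path
#' @return a `bd_scenario`
#' @export
make_plasmid <- function(dLk = 0, epsilon = 0, seed = 1,
                         n_beads = .PLASMID_BEADS,
                         start = c("plectoneme", "circle")) {
  start <- match.arg(start)
  if (abs(dLk) > 20) stop("|dLk| > 20 is outside the studied range")
  sites <- c(E = 1L, P = as.integer(1L + n_beads %/% 2L))
  aff <- data.frame(a = sites[["E"]], b = sites[["P"]], epsilon = epsilon)
  ff <- ff_dna(epsilon)
  bpb <- .PLASMID_BP / n_beads
  if (dLk == 0 || start == "circle") {
    sys <- circular_chain(n_beads, dLk, bead_diameter_nm = 3,
                          bp_per_bead = bpb, sites = sites,
                          affinity_pairs = aff)
  } else {
    sys <- .build_supercoiled(n_beads, dLk, ff, 3, bpb, sites, aff)
  }
  if (epsilon > 0) sys <- .capture_sites(sys, ff, dLk)
  validate_system(sys, ff)
  .new_scenario(sys, ff, list(kind = "plasmid", dLk = dLk, epsilon = epsilon,
                              seed = seed, n_beads = n_beads, start = start))
}

# one chromatin loop (30 nm beads, 60 nm persistence length) with an
# enhancer/promoter pair at the given bead separation
.chromatin_loop <- function(dLk, epsilon, separation_beads,
                            n_beads = .LOOP_BEADS, k_dihedral = 50,
                            align_sites = TRUE, capture = TRUE) {
  if (separation_beads > n_beads / 2)
    stop("separation exceeds half the loop; the shorter arc is ambiguous")
  sites <- c(E = 1L, P = as.integer(1L + separation_beads))
  aff <- data.frame(a = sites[["E"]], b = sites[["P"]], epsilon = epsilon)
  ff <- ff_chromatin(epsilon, k_dihedral = k_dihedral)
  if (dLk == 0) {
    sys <- circular_chain(n_beads, 0, bead_diameter_nm = 30,
                          bp_per_bead = .LOOP_BP_PER_BEAD, sites = sites,
                          affinity_pairs = aff)
  } else {
    sys <- .build_supercoiled(n_beads, dLk, ff, 30, .LOOP_BP_PER_BEAD,
                              sites, aff, align_sites = align_sites)
  }
  if (capture && epsilon > 0) sys <- .capture_sites(sys, ff, dLk)
  list(sys = sys, ff = ff)
}

#' Single dilute chromatin loop scenario
#'
#' One 200-bead chromatin loop (~800 kb topological domain) with an
#' enhancer and a promoter separated by `separation_beads` along the
#' contour (default 100 beads, ~400 kb).
#'
#' @inheritParams make_plasmid
#' @param separation_beads contour separation of the two sites, beads
#' @param n_beads loop size
#' @param k_dihedral torsional stiffness (kT); exposed for the writhe
#'   calibration
#' @export
make_chromatin_loop <- function(dLk = 0, epsilon = 0, seed = 1,
                                separation_beads = 100L,
                                n_beads = .LOOP_BEADS, k_dihedral = 50) {
  parts <- .chromatin_loop(dLk, epsilon, separation_beads, n_beads,
                           k_dihedral)
  validate_system(parts$sys, parts$ff)
  .new_scenario(parts$sys, parts$ff,
                list(kind = "chromatin_loop", dLk = dLk, epsilon = epsilon,
                     seed = seed, separation_beads = separation_beads,
                     n_beads = n_beads, k_dihedral = k_dihedral))
}

#' Crowded periodic box of chromatin loops
#'
#' `n_copies` independent 200-bead chromatin loops in a periodic cubic
#' box sized so the total bead volume occupies `volume_fraction` of it
#' (edge `(n_total pi/6 / phi)^(1/3)`, about 21.9 d for 20 loops at
#' 20 %). Each loop carries one enhancer-promoter pair (affinity strictly
#' intra-loop) at `separation_beads` along the contour. Copies are placed
#' on a jittered grid with random orientations and pushed apart by a
#' capped-displacement zero-temperature relaxation; excluded volume acts
#' between all loops.
#'
#' @inheritParams make_chromatin_loop
#' @param n_copies number of loop copies
#' @param volume_fraction target bead volume fraction (0, 0.5)
#' @export
make_crowded_loops <- function(n_copies = 20L, dLk = -20, epsilon = 8,
                               separation_beads = 100L, volume_fraction = 0.2,
                               seed = 1, n_beads = .LOOP_BEADS) {
  stopifnot(n_copies >= 1, volume_fraction > 0, volume_fraction < 0.5)
  n_total <- n_copies * n_beads
  edge <- (n_total * (pi / 6) / volume_fraction)^(1 / 3)
  parts <- .chromatin_loop(dLk, epsilon, separation_beads, n_beads)
  template <- parts$sys
  ff <- parts$ff
  tmpl_pos <- sweep(template$positions, 2, colMeans(template$positions))
  set.seed(seed)
  k <- ceiling(n_copies^(1 / 3))
  cells <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  cells <- cells[sample.int(nrow(cells), n_copies), , drop = FALSE]
  for (attempt in 1:3) {
    pos <- matrix(0, n_total, 3)
    frm <- matrix(0, n_total, 3)
    for (i in seq_len(n_copies)) {
      R <- .random_rotation()
      centre <- (as.numeric(cells[i, ]) - 0.5) / k * edge +
        runif(3, -0.05, 0.05) * edge
      idx <- (i - 1L) * n_beads + seq_len(n_beads)
      pos[idx, ] <- tmpl_pos %*% t(R) + matrix(centre, n_beads, 3,
                                               byrow = TRUE)
      frm[idx, ] <- template$frames %*% t(R)
    }
    rings <- cbind(start = 1L + (seq_len(n_copies) - 1L) * n_beads,
                   n = n_beads, closed = 1L)
    sites <- integer(0)
    aff <- NULL
    for (i in seq_len(n_copies)) {
      off <- (i - 1L) * n_beads
      sites <- c(sites, setNames(c(off + 1L, off + 1L + separation_beads),
                                 paste0(c("E", "P"), i)))
      aff <- rbind(aff, data.frame(a = off + 1L,
                                   b = off + 1L + separation_beads,
                                   epsilon = epsilon))
    }
    sys <- bead_system(pos, rings = rings, frames = frm,
                       bead_diameter_nm = 30,
                       bp_per_bead = .LOOP_BP_PER_BEAD, sites = sites,
                       affinity_pairs = aff, box = edge)
    # push-off, thermal unjamming, then a final quench
    sys <- .prerelax(sys, ff, n_steps = 3000 * attempt, max_disp = 0.04)
    sys <- .prerelax(sys, ff, n_steps = 4000 * attempt, dt = 1e-4,
                     max_disp = 0.04, kT = 1, seed = seed + attempt)
    sys <- .prerelax(sys, ff, n_steps = 3000, max_disp = 0.04)
    if (epsilon > 0) sys <- .capture_sites(sys, ff, dLk, seed = seed)
    sys <- .set_twist(sys, dLk)
    ok <- tryCatch({
      validate_system(sys, ff)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      return(.new_scenario(sys, ff, list(
        kind = "crowded_loops", dLk = dLk, epsilon = epsilon, seed = seed,
        n_copies = n_copies, separation_beads = separation_beads,
        volume_fraction = volume_fraction, n_beads = n_beads)))
    }
  }
  stop("packing failure: could not relax the crowded box into a valid state")
}

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Recompute the bead volume fraction of a periodic system
#' @param system a `bead_system` with a finite box
#' @export
bead_volume_fraction <- function(system) {
  if (!is.finite(system$box)) stop("system has no periodic box")
  n_beads(system) * (pi / 6) / system$box^3
}

#' Two tethered topological domains
#'
#' Two 200-bead chromatin loops joined by a single permanent harmonic
#' bond between one border bead of each, modelling neighbouring
#' topological domains. One enhancer E sits on loop 1; promoter P1 is on
#' loop 1 and promoter P2 on loop 2, both at the same genomic (contour)
#' distance from E, counting the tether bond as one step for P2. Both
#' pairs carry the same affinity (default 8 kT) and their contacts are
#' tracked independently.
#'
#' @inheritParams make_chromatin_loop
#' @param separation_beads genomic distance from E to each promoter, beads
#' @export
make_tethered_pair <- function(dLk = 0, epsilon = 8, seed = 1,
                               separation_beads = 100L,
                               n_beads = .LOOP_BEADS) {
  half <- separation_beads %/% 2L
  # no contour roll: bead 1 (the tether bead) stays at a plectoneme
  # apex, so the two interwound domains extend away from each other;
  # E and P1 sit half a contour apart, which an interwound juxtaposes
  # naturally
  parts1 <- .chromatin_loop(dLk, 0, separation_beads, n_beads,
                            align_sites = FALSE)
  ff <- ff_chromatin(epsilon)
  loop <- parts1$sys
  # loop 1 as built; loop 2 rotated half a turn and placed so its border
  # bead faces loop 1's border bead across one bond length
  p_t1 <- loop$positions[1, ]
  ctr1 <- colMeans(loop$positions)
  u <- p_t1 - ctr1
  u <- if (sqrt(sum(u^2)) > 1e-8) u / sqrt(sum(u^2)) else c(1, 0, 0)
  # orient loop 2 about the tether axis so that the two domains extend
  # away from each other: E and the inter-domain promoter must not start
  # adjacent by construction accident
  E_idx <- 1L + half
  P2_local <- 1L + (as.integer(separation_beads) - half - 1L)
  best2 <- NULL
  for (ang in pi * c(0, 1, 0.5, 1.5, 0.25, 0.75, 1.25, 1.75)) {
    # flip the copy end-over-end (about an axis perpendicular to the
    # interwound axis), then spin it about the tether direction
    R2 <- .rotation_about(u, ang) %*% .rotation_about(c(1, 0, 0), pi)
    cand <- loop$positions %*% t(R2)
    cand <- sweep(cand, 2, (p_t1 + 1.1 * u) - cand[1, ], `+`)
    sep <- sum((cand[P2_local, ] - loop$positions[E_idx, ])^2)
    if (is.null(best2) || sep > best2$sep)
      best2 <- list(R = R2, pos = cand, sep = sep)
  }
  pos2 <- best2$pos
  frm2 <- loop$frames %*% t(best2$R)
  pos <- rbind(loop$positions, pos2)
  frm <- rbind(loop$frames, frm2)
  rings <- cbind(start = c(1L, n_beads + 1L), n = n_beads, closed = 1L)
  E <- 1L + half
  P1 <- E + as.integer(separation_beads)
  P2 <- n_beads + 1L + (as.integer(separation_beads) - half - 1L)
  sites <- c(E = E, P1 = P1, P2 = P2,
             T1 = 1L, T2 = n_beads + 1L)
  aff <- data.frame(a = c(E, E), b = c(P1, P2), epsilon = epsilon)
  tether <- data.frame(a = 1L, b = n_beads + 1L, k = 200, r0 = 1)
  sys <- bead_system(pos, rings = rings, frames = frm, bead_diameter_nm = 30,
                     bp_per_bead = .LOOP_BP_PER_BEAD, sites = sites,
                     affinity_pairs = aff, extra_bonds = tether)
  sys <- .prerelax(sys, ff, n_steps = 5000, max_disp = 0.04)
  sys <- .set_twist(sys, dLk)
  # start the intra-domain pair bound; the inter-domain contact is the
  # measured outcome and starts from the packed geometry
  sys <- .capture_sites(sys, ff, dLk,
                        pairs = data.frame(a = E, b = P1, epsilon = epsilon))
  validate_system(sys, ff)
  .new_scenario(sys, ff, list(kind = "tethered_pair", dLk = dLk,
                              epsilon = epsilon, seed = seed,
                              separation_beads = separation_beads,
                              n_beads = n_beads))
}

.rotation_about <- function(axis, ang) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(ang); s <- sin(ang)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c_ + s * K + (1 - c_) * (a %o% a)
}

#' Genomic-separation sweep
#'
#' One single-loop scenario per genomic separation (default ~16 kb,
#' ~200 kb and ~400 kb, i.e. 4, 50 and 100 beads at 4000 bp/bead), used
#' for the enhancement-index-versus-distance analysis.
#'
#' @inheritParams make_chromatin_loop
#' @param separations_bp genomic separations in base pairs
#' @return named list of `bd_scenario`s (names `s16000`, ...)
#' @export
make_separation_sweep <- function(dLk = 0, epsilon = 8,
                                  separations_bp = c(16000, 200000, 400000),
                                  seed = 1, n_beads = .LOOP_BEADS) {
  out <- lapply(separations_bp, function(s) {
    sb <- bp_to_beads(s, .LOOP_BP_PER_BEAD)
    sc <- make_chromatin_loop(dLk, epsilon, seed, separation_beads = sb,
                              n_beads = n_beads)
    sc$config$kind <- "separation_sweep"
    sc$config$separation_bp <- s
    sc
  })
  names(out) <- paste0("s", format(separations_bp, scientific = FALSE,
                                   trim = TRUE))
  out
}

#' Two-state Markov telegraph generator
#'
#' Exact (Gillespie) simulation of a two-state on/off Markov process with
#' switching rates `k_on` (off to on) and `k_off` (on to off), sampled on
#' a uniform grid. Stationary fraction-on is `k_on / (k_on + k_off)` and
#' mean dwell times are `1/k_off` (on) and `1/k_on` (off); used to
#' validate the dwell-time estimators against closed forms.
#'
#' @param k_on,k_off switching rates (1/time, positive)
#' @param duration total simulated time
#' @param sample_dt sampling interval
#' @param seed RNG seed
#' @return a `telegraph_signal`
#' @export
make_markov_telegraph <- function(k_on, k_off, duration, sample_dt = 1,
                                  seed = 1) {
  stopifnot(k_on > 0, k_off > 0, duration >= 0, sample_dt > 0)
  n <- floor(duration / sample_dt)
  if (n == 0) return(telegraph_signal(logical(0), sample_dt, "markov"))
  set.seed(seed)
  state <- runif(1) < k_on / (k_on + k_off)
  t_now <- 0
  switch_times <- numeric(0)
  states <- logical(0)
  while (t_now <= duration) {
    switch_times <- c(switch_times, t_now)
    states <- c(states, state)
    t_now <- t_now + rexp(1, rate = if (state) k_off else k_on)
    state <- !state
  }
  grid <- (seq_len(n) - 1) * sample_dt
  on <- states[findInterval(grid, switch_times)]
  telegraph_signal(on, sample_dt, "markov")
}

# ------------------------------------------------------------------- units

#' Base pairs to beads
#' @param bp base pairs (>= 0)
#' @param bp_per_bead base pairs represented by one bead
#' @return nearest-integer bead count
#' @export
bp_to_beads <- function(bp, bp_per_bead) {
  stopifnot(bp >= 0, bp_per_bead > 0)
  as.integer(round(bp / bp_per_bead))
}

#' Thermal energy units to kcal/mol
#' @param x_kBT energy in units of kT
#' @param temperature absolute temperature, K
#' @export
kbt_to_kcal <- function(x_kBT, temperature = 300) {
  stopifnot(x_kBT > 0 || x_kBT == 0, temperature > 0)
  kB <- 1.380649e-23        # J/K
  NA_ <- 6.02214076e23      # 1/mol
  x_kBT * kB * temperature * NA_ / 4184
}

# ------------------------------------------------------------------- config

#' Build a scenario from a configuration list
#'
#' Dispatches on `config$kind` (`plasmid`, `chromatin_loop`,
#' `crowded_loops`, `tethered_pair`, `separation_sweep`). A
#' `separation_sweep` config with a scalar `separation_bp` yields the
#' single corresponding loop; with a vector it yields a named list.
#'
#' @param config list as produced by [read_config()]
#' @export
build_scenario <- function(config) {
  kind <- config$kind %||% stop("config has no scenario kind")
  dLk <- config$dLk %||% 0
  eps <- config$epsilon %||% 0
  seed <- config$seed %||% 1
  switch(kind,
    plasmid = make_plasmid(dLk, eps, seed,
                           n_beads = config$n_beads %||% .PLASMID_BEADS),
    chromatin_loop = make_chromatin_loop(
      dLk, eps, seed,
      separation_beads = config$separation_beads %||% 100L,
      n_beads = config$n_beads %||% .LOOP_BEADS,
      k_dihedral = config$k_dihedral %||% 50),
    crowded_loops = make_crowded_loops(
      n_copies = config$n_copies %||% 20L, dLk = dLk, epsilon = eps,
      separation_beads = config$separation_beads %||% 100L,
      volume_fraction = config$volume_fraction %||% 0.2, seed = seed,
      n_beads = config$n_beads %||% .LOOP_BEADS),
    tethered_pair = make_tethered_pair(
      dLk, eps, seed,
      separation_beads = config$separation_beads %||% 100L,
      n_beads = config$n_beads %||% .LOOP_BEADS),
    separation_sweep = {
      seps <- config$separation_bp %||% c(16000, 200000, 400000)
      if (length(seps) == 1) {
        sc <- make_separation_sweep(dLk, eps, seps, seed)[[1]]
        sc
      } else {
        make_separation_sweep(dLk, eps, seps, seed)
      }
    },
    stop(sprintf("unknown scenario kind '%s'", kind))
  )
}
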