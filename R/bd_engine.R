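# Overdamped Brownian-dynamics propagation with deterministic seeding,
# sampling/equilibration bookkeeping and trajectory containers.

#' Simulation schedule
#'
#' Times are in reduced units (d^2 gamma / kT). The default timestep
#' 1e-4 is stable for the stiff default bonds; runs that trip the
#' topology-conservation check should halve it.
#'
#' @param n_steps number of integration steps.
#' @param dt timestep, reduced units.
#' @param sample_every record an observation every this many steps.
#' @param seed integer seed; identical seed and inputs give bit-identical
#'   trajectories on one platform.
#' @param kT thermal energy (reduced; 0 gives deterministic steepest
#'   descent).
#' @param gamma_r rotational drag of the twist degrees of freedom
#'   (gamma d^2 / 3 for a bead-sized cylinder; only kinetic prefactors,
#'   not equilibrium averages, depend on it).
#' @param equilibration_multiple run-length requirement in multiples of
#'   the estimated equilibration time (40 for DNA, 10 for chromatin);
#'   recorded in the trajectory metadata and checked by
#'   [estimate_equilibration()].
#' @param max_disp cap on the per-step displacement of any bead (d);
#'   0 disables. Used by the scenario builders for overlap push-off,
#'   not during production dynamics.
#' @export
bd_schedule <- function(n_steps, dt = 1e-4, sample_every = 1000, seed = 1,
                        kT = 1, gamma_r = 1 / 3,
                        equilibration_multiple = 40, max_disp = 0) {
  stopifnot(dt > 0, sample_every >= 1, n_steps >= 0)
  structure(list(n_steps = n_steps, dt = dt, sample_every = sample_every,
                 seed = seed, kT = kT, gamma_r = gamma_r,
                 equilibration_multiple = equilibration_multiple,
                 max_disp = max_disp),
            class = "bd_schedule")
}

#' Single Brownian-dynamics step
#'
#' Positions follow the overdamped Euler-Maruyama update
#' `dx = F dt + sqrt(2 kT dt) xi` (drag gamma = 1); the material frame of
#' each edge is transported with the moving edge and then rotated about
#' the new tangent by the twist torque times `dt / gamma_r` plus
#' rotational noise.
#'
#' @param system a `bead_system`
#' @param ff a `force_field`
#' @param dt timestep
#' @param seed RNG seed for the noise of this step
#' @param kT thermal energy (0 for a pure drift step)
#' @param gamma_r rotational drag
#' @return the updated `bead_system`
#' @export
bd_step <- function(system, ff, dt = 1e-4, seed = 1, kT = 1, gamma_r = 1 / 3) {
  res <- cs_run(system$positions, system$frames, .rings0(system$rings),
                .ff_list(system, ff), dt, 1, 1L, as.double(seed), kT, gamma_r,
                FALSE, matrix(integer(), ncol = 2), TRUE, FALSE, 0)
  out <- system
  out$positions <- res$positions
  out$frames <- res$frames
  out
}

#' Run Brownian dynamics and collect a trajectory
#'
#' Propagates a system (or a scenario from the `make_*` generators) and
#' records, at every sampling point, per-ring writhe and twist, radius of
#' gyration, tracked site-pair distances and (optionally) full
#' position/frame snapshots. When `burnin = TRUE` the stretch before the
#' estimated equilibration point (5 integrated autocorrelation times of
#' the writhe, or of the radius of gyration for torsionally relaxed runs,
#' capped at half the run) is discarded from the observations.
#'
#' @param x a `bead_system` or a `bd_scenario`
#' @param schedule a [bd_schedule()]
#' @param ff force field; taken from the scenario if `x` is one
#' @param record_frames keep full snapshots (needed for
#'   [persistence_length()] and [write_trajectory()])
#' @param track_pairs 2-column matrix of bead indices whose distances are
#'   recorded; defaults to the system's affinity pairs, falling back to
#'   all pairs of labelled sites
#' @param burnin discard the pre-equilibration stretch
#' @param record_energy also record the energy breakdown at samples
#' @param use_neighbor_list toggle the Verlet/cell neighbor list (results
#'   are identical with and without; all-pairs is only for testing)
#' @return a `bd_trajectory`
#' @export
bd_run <- function(x, schedule, ff = NULL, record_frames = FALSE,
                   track_pairs = NULL, burnin = TRUE, record_energy = FALSE,
                   use_neighbor_list = TRUE) {
  if (inherits(x, "bd_scenario")) {
    system <- x$system
    ff <- ff %||% x$ff
    scenario_id <- x$config$kind %||% "custom"
  } else {
    system <- x
    scenario_id <- "custom"
  }
  if (is.null(ff)) stop("a force field is required")
  if (is.null(track_pairs)) {
    if (nrow(system$affinity_pairs)) {
      track_pairs <- cbind(system$affinity_pairs$a, system$affinity_pairs$b)
    } else if (length(system$sites) >= 2) {
      cmb <- utils::combn(as.integer(system$sites), 2)
      track_pairs <- t(cmb)
    } else {
      track_pairs <- matrix(integer(), ncol = 2)
    }
  }
  track_pairs <- matrix(as.integer(track_pairs), ncol = 2)
  res <- cs_run(system$positions, system$frames, .rings0(system$rings),
                .ff_list(system, ff), schedule$dt, schedule$n_steps,
                as.integer(schedule$sample_every), as.double(schedule$seed),
                schedule$kT, schedule$gamma_r, record_frames, track_pairs - 1L,
                use_neighbor_list, record_energy, schedule$max_disp)
  final <- system
  final$positions <- res$positions
  final$frames <- res$frames

  pair_names <- .pair_labels(system, track_pairs)
  traj <- structure(list(
    times = as.numeric(res$times),
    wr = res$wr, tw = res$tw, rg = as.numeric(res$rg),
    dists = `colnames<-`(res$dists, pair_names),
    energies = if (record_energy) res$energies else NULL,
    snapshots = if (record_frames) res$snapshots else NULL,
    final = final,
    meta = list(seed = schedule$seed, dt = schedule$dt,
                sample_every = schedule$sample_every,
                n_steps = schedule$n_steps, kT = schedule$kT,
                gamma_r = schedule$gamma_r, scenario = scenario_id,
                ff = unclass(ff), rings = system$rings, box = system$box,
                sites = system$sites,
                bead_diameter_nm = system$bead_diameter_nm,
                bp_per_bead = system$bp_per_bead,
                track_pairs = track_pairs,
                equilibration = NULL, n_discarded = 0L)
  ), class = "bd_trajectory")
  if (burnin) traj <- discard_burnin(traj)
  traj
}

.pair_labels <- function(system, track_pairs) {
  if (!nrow(track_pairs)) return(character())
  lab <- function(i) {
    hit <- names(system$sites)[match(i, system$sites)]
    ifelse(is.na(hit), as.character(i), hit)
  }
  paste0("d_", lab(track_pairs[, 1]), ".", lab(track_pairs[, 2]))
}

#' Sampling interval of a trajectory in reduced time
#' @param traj a `bd_trajectory`
#' @export
sample_dt <- function(traj) traj$meta$dt * traj$meta$sample_every

#' Drop the pre-equilibration stretch of a trajectory
#'
#' The equilibration observable is the writhe of the first ring when the
#' system carries torsional stress, otherwise the radius of gyration.
#' The burn-in is 5 integrated autocorrelation times, capped at half the
#' samples; nothing is discarded for runs shorter than 100 samples.
#'
#' @param traj a `bd_trajectory`
#' @export
discard_burnin <- function(traj) {
  ns <- length(traj$times)
  if (ns < 100) return(traj)
  stressed <- any(abs(traj$tw[1, ]) > 0.5, na.rm = TRUE) ||
    any(abs(traj$wr[1, ]) > 0.5, na.rm = TRUE)
  series <- if (stressed) traj$wr[, 1] else traj$rg
  eq <- suppressWarnings(estimate_equilibration(series, sample_dt(traj)))
  if (!is.finite(eq)) return(traj)
  tau_samples <- eq / sample_dt(traj)
  drop <- min(ceiling(5 * tau_samples), floor(ns / 2))
  keep <- seq.int(drop + 1L, ns)
  traj$times <- traj$times[keep]
  traj$wr <- traj$wr[keep, , drop = FALSE]
  traj$tw <- traj$tw[keep, , drop = FALSE]
  traj$rg <- traj$rg[keep]
  traj$dists <- traj$dists[keep, , drop = FALSE]
  if (!is.null(traj$energies)) traj$energies <- traj$energies[keep, , drop = FALSE]
  if (!is.null(traj$snapshots)) traj$snapshots <- traj$snapshots[keep]
  traj$meta$equilibration <- list(
    tau = unclass(eq), observable = if (stressed) "writhe" else "rg",
    converged = attr(eq, "converged"))
  traj$meta$n_discarded <- traj$meta$n_discarded + as.integer(drop)
  traj
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory> %d samples, t = %.4g .. %.4g (dt_sample = %.3g)\n",
              length(x$times), min(x$times), max(x$times), sample_dt(x)))
  cat(sprintf("  %d bead(s), %d ring(s), scenario '%s', seed %s\n",
              n_beads(x$final), nrow(x$meta$rings), x$meta$scenario,
              format(x$meta$seed)))
  if (x$meta$n_discarded > 0)
    cat(sprintf("  %d pre-equilibration samples discarded (tau = %.3g)\n",
                x$meta$n_discarded, x$meta$equilibration$tau))
  invisible(x)
}

#' Observations of a trajectory as a tibble
#'
#' One row per retained sample: time, radius of gyration, per-ring writhe
#' and twist (columns `wr`, `tw` for a single ring, `wr_k` otherwise) and
#' the tracked site-pair distances.
#'
#' @param x a `bd_trajectory`
#' @param ... unused
#' @export
tidy.bd_trajectory <- function(x, ...) {
  n_rings <- ncol(x$wr)
  out <- tibble::tibble(time = x$times, rg = x$rg)
  if (n_rings == 1) {
    out$wr <- x$wr[, 1]
    out$tw <- x$tw[, 1]
  } else {
    for (r in seq_len(n_rings)) {
      out[[paste0("wr_", r)]] <- x$wr[, r]
      out[[paste0("tw_", r)]] <- x$tw[, r]
    }
  }
  for (nm in colnames(x$dists)) out[[nm]] <- x$dists[, nm]
  out
}

# ------------------------------------------------------------- equilibration

#' Integrated autocorrelation time of a scalar series
#'
#' Sokal's self-consistent windowing estimate
#' `tau = (1/2 + sum_k rho_k) * dt_sample`, summed up to the first window
#' `W >= c * tau` (c = 5). Used to set the burn-in and to check the
#' 40x / 10x run-length requirement. A series whose estimated tau exceeds
#' a tenth of its length is flagged as unequilibrated via the
#' `converged` attribute (with a warning), as is a constant series.
#'
#' @param series numeric vector (at least 100 samples)
#' @param dt_sample spacing between samples (reduced time)
#' @return tau in the units of `dt_sample`, with attribute `converged`
#' @export
estimate_equilibration <- function(series, dt_sample = 1) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 100) stop("need at least 100 samples to estimate equilibration")
  if (var(series) == 0 || !is.finite(var(series))) {
    warning("constant or non-finite series: equilibration not estimable")
    return(structure(NA_real_, converged = FALSE))
  }
  rho <- acf(series, lag.max = min(n - 2, 2000), plot = FALSE,
             demean = TRUE)$acf[-1]
  tau <- 0.5
  closed <- FALSE
  for (k in seq_along(rho)) {
    tau <- tau + rho[k]
    if (k >= 5 * tau) {
      closed <- TRUE
      break
    }
  }
  tau <- max(tau, 0.5)
  # unreliable when the summation window never closes (long-memory /
  # drifting series) or the estimate is not well below the series length
  converged <- closed && is.finite(tau) && tau <= n / 10
  if (!converged)
    warning(sprintf("series looks unequilibrated: tau = %.3g samples for n = %d",
                    tau, n))
  structure(tau * dt_sample, converged = converged)
}
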