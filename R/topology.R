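# Writhe, twist, linking-number bookkeeping (Lk = Tw + Wr), supercoiling
# density and persistence-length estimation.

#' Writhe of closed ring(s)
#'
#' Exact discrete Gauss double integral: the signed solid angle of every
#' non-adjacent segment pair is evaluated in closed form and summed.
#' Right-handed convention; negatively supercoiled plectonemes have
#' negative writhe. Quadratic in the number of beads.
#'
#' @param x a `bead_system`, or an n x 3 matrix of positions interpreted
#'   as one closed ring
#' @return numeric vector, one writhe per ring (NA for open chains)
#' @export
writhe <- function(x) {
  if (is.matrix(x)) return(cs_writhe(x, cbind(0L, nrow(x), 1L)))
  cs_writhe(x$positions, .rings0(x$rings))
}

#' Total twist of closed ring(s), in turns
#'
#' Sum of the per-junction material twist angles divided by 2 pi.
#'
#' @param x a `bead_system`
#' @export
twist <- function(x) {
  phis <- cs_phis(x$positions, x$frames, .rings0(x$rings))
  vapply(seq_len(nrow(x$rings)), function(r) {
    if (x$rings[r, "closed"] != 1L) return(NA_real_)
    idx <- x$rings[r, "start"] + seq_len(x$rings[r, "n"]) - 1L
    sum(phis[idx]) / (2 * pi)
  }, numeric(1))
}

#' Linking number (deficit) of closed ring(s)
#'
#' `Lk = Tw + Wr`. Because twist is measured against the relaxed
#' (helically unstressed) reference, this is the linking-number deficit
#' dLk relative to the relaxed ring, the quantity that the dynamics
#' conserves.
#'
#' @param x a `bead_system`
#' @export
linking_number <- function(x) twist(x) + writhe(x)

#' Topology state of every ring, as a tibble
#'
#' @param x a `bead_system`
#' @param helical_repeat base pairs per helical turn used for Lk0
#' @return tibble with columns ring, n_beads, wr, tw, lk (= dLk) and,
#'   when the system knows its bp-per-bead, n_bp, lk0 and sigma
#' @export
topology_state <- function(x, helical_repeat = 10.5) {
  wr <- writhe(x)
  tw <- twist(x)
  out <- tibble::tibble(ring = seq_along(wr),
                        n_beads = as.integer(x$rings[, "n"]),
                        wr = wr, tw = tw, lk = tw + wr)
  if (!is.null(x$bp_per_bead)) {
    out$n_bp <- out$n_beads * x$bp_per_bead
    out$lk0 <- out$n_bp / helical_repeat
    out$sigma <- out$lk / out$lk0
  }
  out
}

#' Supercoiling density
#'
#' `sigma = dLk / Lk0` with `Lk0 = n_bp / helical_repeat`; a
#' size-independent measure of torsional stress (e.g. dLk = -15 on a
#' 3000 bp plasmid gives sigma = -0.0525, i.e. about -0.05).
#'
#' @param dLk linking-number deficit, turns
#' @param n_bp length in base pairs
#' @param helical_repeat bp per turn of the relaxed double helix
#' @export
supercoiling_density <- function(dLk, n_bp, helical_repeat = 10.5) {
  stopifnot(n_bp > 0)
  dLk / (n_bp / helical_repeat)
}

#' Fraction of the imposed linking deficit stored as writhe
#'
#' Computes `<|Wr|> / |dLk|` over an (equilibrated) trajectory, the
#' calibration quantity of the DNA parameterization (about 0.8 at
#' dLk = -15). The signed writhe is sign-locked to the imposed deficit
#' before averaging; at the studied supercoiling densities no sign flips
#' occur.
#'
#' @param traj a `bd_trajectory`
#' @param dLk the imposed linking-number deficit (non-zero)
#' @param ring which ring to analyse
#' @param conf bootstrap confidence level
#' @param B number of moving-block bootstrap replicates
#' @return tibble with `fraction`, `mean_wr`, `ci_lo`, `ci_hi`, `n`
#' @export
writhe_fraction <- function(traj, dLk, ring = 1, conf = 0.95, B = 200) {
  if (dLk == 0) stop("writhe fraction is undefined at dLk = 0")
  wr <- traj$wr[, ring]
  locked <- sign(dLk) * wr
  bl <- .boot_block_length(locked)
  bt <- .block_boot(locked, function(v) mean(v) / abs(dLk), B, bl)
  al <- (1 - conf) / 2
  tibble::tibble(fraction = mean(locked) / abs(dLk),
                 mean_wr = mean(locked),
                 ci_lo = quantile(bt, al, names = FALSE),
                 ci_hi = quantile(bt, 1 - al, names = FALSE),
                 n = length(wr))
}

# ---------------------------------------------------------------- persistence

#' Persistence length from tangent correlations
#'
#' Fits `<t(0) . t(s)> = exp(-s / P)` over contour separations up to two
#' persistence lengths (iterated once from an initial slope estimate),
#' restricted to well under half the ring contour where the closure
#' correction is negligible. Needs a trajectory recorded with
#' `record_frames = TRUE` from a torsionally relaxed run.
#'
#' @param traj a `bd_trajectory` with snapshots, or a list of replicate
#'   trajectories of the same system (their tangent correlations are
#'   pooled before fitting)
#' @param ring which ring to analyse
#' @return persistence length in nm (bond length = bead diameter), with
#'   attribute `beads` giving it in bond lengths
#' @export
persistence_length <- function(traj, ring = 1) {
  if (!inherits(traj, "bd_trajectory")) {
    merged <- traj[[1]]
    merged$snapshots <- do.call(c, lapply(traj, `[[`, "snapshots"))
    traj <- merged
  }
  if (is.null(traj$snapshots)) stop("trajectory was not recorded with frames")
  rg <- traj$meta$rings[ring, ]
  idx <- rg["start"] + seq_len(rg["n"]) - 1L
  n <- rg[["n"]]
  closed <- rg[["closed"]] == 1L
  smax <- if (closed) max(3L, n %/% 4L) else max(3L, (n - 1L) %/% 2L)
  corr <- numeric(smax)
  wt <- numeric(smax)
  for (snap in traj$snapshots) {
    pos <- snap[idx, 1:3, drop = FALSE]
    if (closed) {
      tang <- pos[c(2:n, 1), ] - pos
      tang <- tang / sqrt(rowSums(tang^2))
      for (s in seq_len(smax)) {
        corr[s] <- corr[s] +
          sum(rowSums(tang * tang[c((s + 1):n, seq_len(s)), ]))
        wt[s] <- wt[s] + n
      }
    } else {
      tang <- diff(pos)
      tang <- tang / sqrt(rowSums(tang^2))
      m <- nrow(tang)
      for (s in seq_len(min(smax, m - 1L))) {
        corr[s] <- corr[s] +
          sum(rowSums(tang[seq_len(m - s), , drop = FALSE] *
                        tang[(1 + s):m, , drop = FALSE]))
        wt[s] <- wt[s] + (m - s)
      }
    }
  }
  corr <- corr / pmax(wt, 1)
  fit_window <- function(wmax) {
    s <- seq_len(max(3L, min(wmax, smax)))
    s <- s[corr[s] > 0.05]
    if (length(s) < 2) return(NA_real_)
    -1 / coef(lm(log(corr[s]) ~ s))[[2]]
  }
  if (corr[1] <= 0 || corr[2] <= 0 || corr[2] >= corr[1])
    stop("tangent correlation does not decay; persistence length not fittable")
  # fit window: two persistence lengths, seeded by the short-range
  # decrement; the window is not re-grown from the fit itself, which
  # would creep up the slowly decaying excluded-volume tail of very
  # flexible chains
  p_seed <- 1 / log(corr[1] / corr[2])
  p <- fit_window(ceiling(2 * p_seed))
  if (!is.finite(p) || p <= 0)
    stop("tangent correlation does not decay; persistence length not fittable")
  if (2 * max(p, p_seed) > smax)
    warning(sprintf(paste0("fit window truncated by chain size: P = %.3g beads ",
                           "but only s <= %d available"), max(p, p_seed), smax))
  structure(p * traj$meta$bead_diameter_nm, beads = p)
}

# ------------------------------------------------------------ block bootstrap

# moving-block bootstrap over a (possibly autocorrelated) series
.block_boot <- function(x, statfun, B = 200, block_len = NULL) {
  n <- length(x)
  bl <- max(1L, min(as.integer(block_len %||% .boot_block_length(x)), n))
  n_blocks <- ceiling(n / bl)
  vapply(seq_len(B), function(b) {
    starts <- sample.int(n - bl + 1L, n_blocks, replace = TRUE)
    idx <- as.vector(outer(0:(bl - 1L), starts, `+`))[seq_len(n)]
    statfun(x[idx])
  }, numeric(1))
}

# block length: 5 integrated autocorrelation times of the series
.boot_block_length <- function(x) {
  if (length(x) < 100 || var(x) == 0) return(max(1L, length(x) %/% 20L))
  tau <- suppressWarnings(estimate_equilibration(x, 1))
  if (!is.finite(tau)) return(max(1L, length(x) %/% 20L))
  max(1L, as.integer(ceiling(5 * tau)))
}
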