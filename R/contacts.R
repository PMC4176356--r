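# Telegraph signals, dwell-time statistics, enhancement and preference
# indices, and the fraction-on phase diagram.

#' Binary contact telegraph from a trajectory
#'
#' Two sites are "on" when their centre-to-centre distance is below the
#' threshold of two bead diameters (6 nm for 3 nm beads), with
#' minimum-image distances under periodic boundary conditions. Each site
#' pair yields its own telegraph; telegraphs of one enhancer with two
#' promoters are not mutually exclusive.
#'
#' @param traj a `bd_trajectory`
#' @param site_a,site_b bead indices or site labels (e.g. `"E"`, `"P1"`)
#' @param threshold contact threshold, in bead diameters
#' @return a `telegraph_signal`: tibble with columns `time` and `on`,
#'   carrying the sampling interval and pair label as attributes
#' @export
telegraph <- function(traj, site_a, site_b, threshold = 2) {
  a <- .resolve_site(traj, site_a)
  b <- .resolve_site(traj, site_b)
  tp <- traj$meta$track_pairs
  hit <- which((tp[, 1] == a & tp[, 2] == b) | (tp[, 1] == b & tp[, 2] == a))
  if (length(hit)) {
    d <- traj$dists[, hit[1]]
  } else if (!is.null(traj$snapshots)) {
    box <- traj$meta$box
    d <- vapply(traj$snapshots, function(s) {
      dx <- s[a, 1:3] - s[b, 1:3]
      if (is.finite(box)) dx <- dx - box * round(dx / box)
      sqrt(sum(dx^2))
    }, numeric(1))
  } else {
    stop("site pair was not tracked and no snapshots are available")
  }
  telegraph_signal(d < threshold, sample_dt(traj),
                   pair = paste0(site_a, "-", site_b))
}

.resolve_site <- function(traj, site) {
  if (is.character(site)) {
    idx <- traj$meta$sites[site]
    if (any(is.na(idx))) stop(sprintf("unknown site label '%s'", site))
    return(as.integer(idx))
  }
  site <- as.integer(site)
  if (site < 1 || site > n_beads(traj$final)) stop("site index out of range")
  site
}

#' Construct a telegraph signal from a logical vector
#'
#' @param on logical vector of on/off states at uniform sampling interval
#' @param dt_sample sampling interval (reduced time)
#' @param pair optional site-pair label
#' @export
telegraph_signal <- function(on, dt_sample = 1, pair = NA_character_) {
  on <- as.logical(on)
  tibble::new_tibble(
    list(time = (seq_along(on) - 1) * dt_sample, on = on),
    nrow = length(on), class = "telegraph_signal",
    dt_sample = dt_sample, pair = pair)
}

#' Dwell-time statistics of a telegraph signal
#'
#' Run-length encodes the signal. The fraction-on is the exact ratio of
#' on-samples to all samples. Mean dwell times use only interior
#' (uncensored) runs: the first and last runs touch the observation
#' window boundary, so their durations are right/left-censored and would
#' bias the means; they still count toward the fraction-on. A state with
#' no interior runs gets `NA` dwell statistics rather than a fabricated
#' value. Confidence intervals come from a moving-block bootstrap with
#' block length five integrated autocorrelation times.
#'
#' Off-time distributions under strong supercoiling are heavy-tailed
#' (occasional very long excursions when the sites slither apart), so
#' medians are reported alongside the means.
#'
#' @param signal a `telegraph_signal` (or logical vector)
#' @param B bootstrap replicates (0 disables the bootstrap)
#' @param conf confidence level
#' @return a `dwell_stats` object; see [tidy.dwell_stats()]
#' @export
dwell_stats <- function(signal, B = 200, conf = 0.95) {
  if (is.logical(signal)) signal <- telegraph_signal(signal)
  on <- signal$on
  dt <- attr(signal, "dt_sample")
  if (length(on) < 2) stop("signal needs at least 2 samples")
  r <- rle(on)
  k <- length(r$lengths)
  interior <- if (k > 2) seq.int(2L, k - 1L) else integer()
  on_runs <- interior[r$values[interior]]
  off_runs <- interior[!r$values[interior]]
  t_on <- r$lengths[on_runs] * dt
  t_off <- r$lengths[off_runs] * dt
  out <- list(
    fraction_on = mean(on),
    mean_t_on = if (length(t_on)) mean(t_on) else NA_real_,
    mean_t_off = if (length(t_off)) mean(t_off) else NA_real_,
    median_t_on = if (length(t_on)) median(t_on) else NA_real_,
    median_t_off = if (length(t_off)) median(t_off) else NA_real_,
    n_on_events = length(t_on),
    n_off_events = length(t_off),
    dt_sample = dt,
    total_time = length(on) * dt,
    pair = attr(signal, "pair"),
    conf = conf)
  if (B > 0 && length(on) >= 10 && var(as.numeric(on)) > 0) {
    bl <- .boot_block_length(as.numeric(on))
    boots <- replicate(B, {
      idx <- .block_idx(length(on), bl)
      o <- on[idx]
      rr <- rle(o)
      kk <- length(rr$lengths)
      ii <- if (kk > 2) seq.int(2L, kk - 1L) else integer()
      c(mean(o),
        mean(rr$lengths[ii[rr$values[ii]]] * dt),
        mean(rr$lengths[ii[!rr$values[ii]]] * dt))
    })
    al <- (1 - conf) / 2
    qs <- apply(boots, 1, quantile, probs = c(al, 1 - al), na.rm = TRUE)
    out$ci <- tibble::tibble(
      statistic = c("fraction_on", "mean_t_on", "mean_t_off"),
      ci_lo = qs[1, ], ci_hi = qs[2, ],
      se = apply(boots, 1, sd, na.rm = TRUE))
  } else {
    out$ci <- tibble::tibble(statistic = character(), ci_lo = double(),
                             ci_hi = double(), se = double())
  }
  structure(out, class = "dwell_stats")
}

.block_idx <- function(n, bl) {
  bl <- max(1L, min(bl, n))
  starts <- sample.int(n - bl + 1L, ceiling(n / bl), replace = TRUE)
  as.vector(outer(0:(bl - 1L), starts, `+`))[seq_len(n)]
}

#' @export
print.dwell_stats <- function(x, ...) {
  cat(sprintf("<dwell_stats>%s fraction_on = %.4f (%d on / %d off interior events)\n",
              if (is.na(x$pair)) "" else paste0(" [", x$pair, "]"),
              x$fraction_on, x$n_on_events, x$n_off_events))
  cat(sprintf("  <t_on>  = %.4g   <t_off> = %.4g   (medians %.4g / %.4g)\n",
              x$mean_t_on, x$mean_t_off, x$median_t_on, x$median_t_off))
  invisible(x)
}

#' Tidy a dwell-stats object
#' @param x a `dwell_stats`
#' @param ... unused
#' @return tibble with statistic, value and bootstrap CI columns
#' @export
tidy.dwell_stats <- function(x, ...) {
  base <- tibble::tibble(
    statistic = c("fraction_on", "mean_t_on", "mean_t_off",
                  "median_t_on", "median_t_off"),
    value = c(x$fraction_on, x$mean_t_on, x$mean_t_off,
              x$median_t_on, x$median_t_off))
  dplyr::left_join(base, x$ci, by = "statistic")
}

#' One-row summary of a dwell-stats object
#' @param x a `dwell_stats`
#' @param ... unused
#' @export
glance.dwell_stats <- function(x, ...) {
  tibble::tibble(fraction_on = x$fraction_on, mean_t_on = x$mean_t_on,
                 mean_t_off = x$mean_t_off, n_on_events = x$n_on_events,
                 n_off_events = x$n_off_events, total_time = x$total_time)
}

# -------------------------------------------------------------------- ratios

#' Enhancement index: fold change of fraction-on versus the relaxed state
#'
#' `fraction_on(dLk) / fraction_on(0)`, the supercoiling enhancement of
#' contact time at fixed affinity and genomic separation. The CI is
#' propagated from the bootstrap standard errors on the log scale.
#'
#' @param stats_at_dLk `dwell_stats` at the supercoiled condition
#' @param stats_at_dLk0 `dwell_stats` at dLk = 0
#' @param zero_denominator `"flag"` reports an undefined fold as `NA`;
#'   `"floor"` reports a lower bound against the denominator's
#'   confidence ceiling (at least one on-sample's worth of fraction),
#'   for windows in which the relaxed state never reached contact
#' @return tibble with `value`, `ci_lo`, `ci_hi`
#' @export
enhancement_index <- function(stats_at_dLk, stats_at_dLk0,
                              zero_denominator = c("flag", "floor")) {
  .fold_ratio(stats_at_dLk, stats_at_dLk0,
              zero_denominator = match.arg(zero_denominator))
}

#' Preference ratio: intra- versus inter-domain contact
#'
#' Ratio of the fraction-on of the intra-domain enhancer-promoter pair to
#' the inter-domain one. The two telegraphs are tracked independently
#' (the enhancer may be in contact with both promoters at once). When the
#' inter-domain fraction-on is exactly zero in the sampled window the
#' ratio is reported as a lower bound computed against the upper
#' confidence limit of the denominator.
#'
#' @param stats_intra,stats_inter `dwell_stats` for the two pairs
#' @export
preference_ratio <- function(stats_intra, stats_inter) {
  .fold_ratio(stats_intra, stats_inter, zero_denominator = "floor")
}

.fold_ratio <- function(num, den, zero_denominator = "flag") {
  f1 <- num$fraction_on
  f0 <- den$fraction_on
  se1 <- .stat_se(num, "fraction_on")
  se0 <- .stat_se(den, "fraction_on")
  if (f0 == 0) {
    if (zero_denominator == "floor") {
      # denominator CI ceiling: at least one on-sample's worth of rate
      floor_f0 <- max(.stat_ci_hi(den, "fraction_on"),
                      den$dt_sample / den$total_time, na.rm = TRUE)
      return(tibble::tibble(value = f1 / floor_f0, ci_lo = NA_real_,
                            ci_hi = Inf, lower_bound = TRUE))
    }
    return(tibble::tibble(value = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, lower_bound = NA))
  }
  ratio <- f1 / f0
  if (is.finite(se1) && is.finite(se0) && f1 > 0) {
    se_log <- sqrt((se1 / f1)^2 + (se0 / f0)^2)
    z <- 1.96
    tibble::tibble(value = ratio, ci_lo = ratio * exp(-z * se_log),
                   ci_hi = ratio * exp(z * se_log), lower_bound = FALSE)
  } else {
    tibble::tibble(value = ratio, ci_lo = NA_real_, ci_hi = NA_real_,
                   lower_bound = FALSE)
  }
}

.stat_se <- function(st, stat) {
  i <- match(stat, st$ci$statistic)
  if (is.na(i)) NA_real_ else st$ci$se[i]
}

.stat_ci_hi <- function(st, stat) {
  i <- match(stat, st$ci$statistic)
  if (is.na(i)) NA_real_ else st$ci$ci_hi[i]
}

# ------------------------------------------------------------- phase diagram

#' Fraction-on phase diagram over (dLk, epsilon)
#'
#' Interpolates a gridded fraction-on surface with bicubic (natural cubic
#' spline, row-then-column) interpolation and extracts isoprobability
#' lines at the requested levels. Grid cells absent from the input are
#' masked and the isolines are clipped around them.
#'
#' @param results data frame with columns `dLk`, `epsilon`, `fraction_on`
#'   (one row per completed run; at least a 2 x 2 grid)
#' @param levels isoline levels of fraction-on
#' @param n_fine fine-grid resolution per axis
#' @return a `phase_diagram`: list with `surface` (fine-grid tibble),
#'   `isolines` (tibble of level paths) and the input `grid`
#' @export
phase_diagram <- function(results, levels = c(0.1, 0.25, 0.5, 0.75),
                          n_fine = 81) {
  stopifnot(all(c("dLk", "epsilon", "fraction_on") %in% names(results)))
  xs <- sort(unique(results$dLk))
  ys <- sort(unique(results$epsilon))
  if (length(xs) < 2 || length(ys) < 2)
    stop("need at least a 2 x 2 grid of (dLk, epsilon) results")
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(results$dLk, xs), match(results$epsilon, ys))] <-
    results$fraction_on
  mask <- is.na(z)
  zf <- .fill_na_grid(z)
  xf <- seq(min(xs), max(xs), length.out = n_fine)
  yf <- seq(min(ys), max(ys), length.out = n_fine)
  fine <- .bicubic(xs, ys, zf, xf, yf)
  if (any(mask)) {
    # re-mask fine cells whose nearest coarse cell was missing
    ix <- vapply(xf, function(v) which.min(abs(xs - v)), integer(1))
    iy <- vapply(yf, function(v) which.min(abs(ys - v)), integer(1))
    fine[mask[cbind(rep(ix, times = length(yf)),
                    rep(iy, each = length(xf)))]] <- NA_real_
  }
  iso <- suppressWarnings(grDevices::contourLines(xf, yf, fine,
                                                  levels = levels))
  rng <- range(fine, na.rm = TRUE)
  if (diff(rng) < 1e-12 && any(abs(levels - rng[1]) < 1e-12)) {
    # constant surface at an isoline level: the whole grid is the level
    # set; report its boundary as one degenerate isoline
    iso <- list(list(level = rng[1],
                     x = c(min(xf), max(xf), max(xf), min(xf), min(xf)),
                     y = c(min(yf), min(yf), max(yf), max(yf), min(yf))))
  }
  isolines <- if (length(iso)) {
    dplyr::bind_rows(lapply(seq_along(iso), function(i) {
      tibble::tibble(line_id = i, level = iso[[i]]$level,
                     dLk = iso[[i]]$x, epsilon = iso[[i]]$y)
    }))
  } else {
    tibble::tibble(line_id = integer(), level = double(), dLk = double(),
                   epsilon = double())
  }
  surface <- tibble::tibble(dLk = rep(xf, times = length(yf)),
                            epsilon = rep(yf, each = length(xf)),
                            fraction_on = as.vector(fine))
  structure(list(surface = surface, isolines = isolines,
                 grid = tibble::as_tibble(results), levels = levels),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d grid points, %d isoline path(s) at levels %s\n",
              nrow(x$grid), length(unique(x$isolines$line_id)),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

# replace missing grid cells by the mean of available neighbours (only for
# the interpolation substrate; masked cells are restored to NA afterwards)
.fill_na_grid <- function(z) {
  while (anyNA(z)) {
    for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
      if (!is.na(z[i, j])) next
      nb <- c(if (i > 1) z[i - 1, j], if (i < nrow(z)) z[i + 1, j],
              if (j > 1) z[i, j - 1], if (j < ncol(z)) z[i, j + 1])
      if (any(!is.na(nb))) z[i, j] <- mean(nb, na.rm = TRUE)
    }
  }
  z
}

# bicubic interpolation by repeated 1-D natural cubic splines
.bicubic <- function(xs, ys, z, xf, yf) {
  tmp <- matrix(0, length(xf), length(ys))
  for (j in seq_along(ys))
    tmp[, j] <- spline(xs, z[, j], xout = xf, method = "natural")$y
  out <- matrix(0, length(xf), length(yf))
  for (i in seq_along(xf))
    out[i, ] <- spline(ys, tmp[i, ], xout = yf, method = "natural")$y
  out
}
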