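# Persistence: structured-text scenario configs (YAML), plain-text
# trajectory container, extended-XYZ snapshot export, TSV result tables
# and run manifests. Files store reduced units plus the nm-per-d and
# bp-per-bead factors in metadata; unit conversions happen at reporting
# time only.

.normalize_config <- function(config) {
  dbl <- c("dLk", "epsilon", "volume_fraction", "dt", "separation_bp",
           "dLk_values", "epsilon_values", "k_dihedral")
  int <- c("seed", "n_beads", "n_copies", "separation_beads", "n_steps",
           "sample_every")
  for (k in intersect(dbl, names(config))) config[[k]] <- as.double(config[[k]])
  for (k in intersect(int, names(config))) config[[k]] <- as.integer(config[[k]])
  config
}

#' Write / read a scenario configuration
#'
#' Flat YAML key-value files with at least a `kind` entry; numeric fields
#' are normalized on both paths so that `read_config(write_config(x))`
#' round-trips exactly.
#'
#' @param config named list (see [build_scenario()] for recognized keys)
#' @param path file path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(.normalize_config(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  config <- yaml::read_yaml(path)
  if (is.null(config$kind)) stop("config has no scenario `kind`")
  .normalize_config(config)
}

# ---------------------------------------------------------------- trajectory

#' Write a trajectory to a plain-text container
#'
#' Self-describing text format: a metadata header (JSON) carrying rings,
#' sites, box, unit factors and the schedule, followed by one block per
#' sample with positions and material frame vectors at 17 significant
#' digits (lossless round trip for doubles).
#'
#' @param traj a `bd_trajectory` recorded with `record_frames = TRUE`
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj$snapshots))
    stop("trajectory has no snapshots; rerun with record_frames = TRUE")
  meta <- traj$meta
  meta$rings <- apply(meta$rings, 1, as.list)
  meta$sites <- as.list(meta$sites)
  meta$track_pairs <- if (nrow(meta$track_pairs))
    apply(meta$track_pairs, 1, as.list) else list()
  meta$equilibration <- NULL
  meta$box <- if (is.finite(meta$box)) meta$box else "unbounded"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coilsim trajectory v1", con)
  writeLines(paste0("#meta ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA)), con)
  n <- nrow(traj$snapshots[[1]])
  for (i in seq_along(traj$snapshots)) {
    writeLines(sprintf("#frame %d time %.17g", i, traj$times[i]), con)
    snap <- traj$snapshots[[i]]
    if (nrow(snap) != n) stop("inconsistent bead count across frames")
    writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                       snap[, 1], snap[, 2], snap[, 3],
                       snap[, 4], snap[, 5], snap[, 6]), con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores positions, frames, box and metadata losslessly and recomputes
#' the derived observables (writhe, twist, radius of gyration, tracked
#' distances) from the snapshots. Corrupt or truncated files raise an
#' error rather than returning a silently shortened trajectory.
#'
#' @param path file path
#' @return a `bd_trajectory`
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "#coilsim trajectory v1")
    stop("not a coilsim trajectory file")
  if (!startsWith(lines[2], "#meta "))
    stop("corrupt trajectory: missing metadata header")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", lines[2]),
                             simplifyVector = TRUE)
  rings <- do.call(rbind, lapply(seq_len(nrow(meta$rings)), function(i)
    as.integer(unlist(meta$rings[i, ]))))
  colnames(rings) <- c("start", "n", "closed")
  n <- sum(rings[, "n"])
  frame_at <- which(startsWith(lines, "#frame"))
  if (!length(frame_at)) stop("corrupt trajectory: no frames")
  times <- as.numeric(sub("^#frame \\d+ time ", "", lines[frame_at]))
  ends <- c(frame_at[-1], length(lines) + 1L)
  snapshots <- vector("list", length(frame_at))
  for (i in seq_along(frame_at)) {
    block <- lines[seq.int(frame_at[i] + 1L, ends[i] - 1L)]
    if (length(block) != n)
      stop(sprintf("corrupt trajectory: frame %d has %d records, expected %d",
                   i, length(block), n))
    vals <- scan(text = block, quiet = TRUE)
    snapshots[[i]] <- matrix(vals, ncol = 6, byrow = TRUE)
  }
  box <- if (identical(meta$box, "unbounded")) Inf else as.numeric(meta$box)
  sites <- unlist(meta$sites)
  sites <- if (length(sites)) setNames(as.integer(sites), names(sites))
           else integer()
  tp <- if (length(meta$track_pairs))
    matrix(as.integer(unlist(meta$track_pairs)), ncol = 2, byrow = TRUE)
  else matrix(integer(), ncol = 2)

  n_rings <- nrow(rings)
  wr <- matrix(NA_real_, length(snapshots), n_rings)
  tw <- matrix(NA_real_, length(snapshots), n_rings)
  rg <- numeric(length(snapshots))
  dists <- matrix(NA_real_, length(snapshots), nrow(tp))
  r0 <- .rings0(rings)
  for (i in seq_along(snapshots)) {
    pos <- snapshots[[i]][, 1:3, drop = FALSE]
    frm <- snapshots[[i]][, 4:6, drop = FALSE]
    wr[i, ] <- cs_writhe(pos, r0)
    phis <- cs_phis(pos, frm, r0)
    tw[i, ] <- vapply(seq_len(n_rings), function(r) {
      idx <- rings[r, "start"] + seq_len(rings[r, "n"]) - 1L
      sum(phis[idx]) / (2 * pi)
    }, numeric(1))
    cen <- sweep(pos, 2, colMeans(pos))
    rg[i] <- sqrt(mean(rowSums(cen^2)))
    if (nrow(tp)) {
      d <- pos[tp[, 1], , drop = FALSE] - pos[tp[, 2], , drop = FALSE]
      if (is.finite(box)) d <- d - box * round(d / box)
      dists[i, ] <- sqrt(rowSums(d^2))
    }
  }
  last <- snapshots[[length(snapshots)]]
  final <- bead_system(last[, 1:3, drop = FALSE], rings = rings,
                       frames = last[, 4:6, drop = FALSE],
                       bead_diameter_nm = meta$bead_diameter_nm,
                       bp_per_bead = meta$bp_per_bead, sites = sites,
                       box = box)
  meta_out <- list(seed = as.numeric(meta$seed), dt = meta$dt,
                   sample_every = meta$sample_every, n_steps = meta$n_steps,
                   kT = meta$kT, gamma_r = meta$gamma_r,
                   scenario = meta$scenario, ff = meta$ff, rings = rings,
                   box = box, sites = sites,
                   bead_diameter_nm = meta$bead_diameter_nm,
                   bp_per_bead = meta$bp_per_bead, track_pairs = tp,
                   equilibration = NULL, n_discarded = 0L)
  structure(list(times = times, wr = wr, tw = tw, rg = rg,
                 dists = `colnames<-`(dists, .pair_labels(final, tp)),
                 energies = NULL, snapshots = snapshots, final = final,
                 meta = meta_out),
            class = "bd_trajectory")
}

# ----------------------------------------------------------------------- xyz

#' Export a single conformation as extended XYZ
#'
#' One atom record per bead with a species label (site labels for special
#' beads, `B` otherwise); the comment line carries the box edge and the
#' current linking-number deficit of each ring.
#'
#' @param system a `bead_system`
#' @param path output file
#' @export
write_xyz <- function(system, path) {
  n <- n_beads(system)
  labels <- rep("B", n)
  if (length(system$sites))
    labels[system$sites] <- names(system$sites)
  lk <- linking_number(system)
  comment <- sprintf("box=%s dLk=%s",
                     if (is.finite(system$box)) format(system$box)
                     else "unbounded",
                     paste(sprintf("%.3f", lk), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(comment, con)
  writeLines(sprintf("%s %.8f %.8f %.8f", labels, system$positions[, 1],
                     system$positions[, 2], system$positions[, 3]), con)
  invisible(path)
}

# ----------------------------------------------------------------- manifests

#' Run manifest
#'
#' Traceability record for a run: scenario configuration, force-field and
#' schedule echoes, seed, package version and the output paths.
#'
#' @param scenario a `bd_scenario`
#' @param schedule a `bd_schedule`
#' @param outputs character vector of file paths this run produced
#' @export
run_manifest <- function(scenario, schedule, outputs = character()) {
  cfg <- scenario$config
  id <- paste(cfg$kind %||% "custom", cfg$dLk %||% 0, cfg$epsilon %||% 0,
              schedule$seed, sep = "_")
  list(id = id, scenario = cfg, force_field = unclass(scenario$ff),
       schedule = unclass(schedule), seed = schedule$seed,
       version = as.character(utils::packageVersion("coilsim")),
       outputs = as.list(outputs))
}

#' @rdname run_manifest
#' @param manifest a manifest list
#' @param path file path (JSON)
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a result table as TSV, stamped with seed and manifest id
#'
#' @param tbl data frame of results
#' @param path output path
#' @param manifest optional manifest (see [run_manifest()]) supplying the
#'   `seed` and `manifest_id` columns when the table lacks them
#' @export
write_results_tsv <- function(tbl, path, manifest = NULL) {
  if (!is.null(manifest)) {
    if (!"seed" %in% names(tbl)) tbl$seed <- manifest$seed
    if (!"manifest_id" %in% names(tbl)) tbl$manifest_id <- manifest$id
  }
  readr::write_tsv(tbl, path)
  invisible(path)
}
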