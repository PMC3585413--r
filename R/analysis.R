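#' Time-averaged migration speed of a trajectory
#'
#' Resamples the nucleus-center track at `sampling_interval` (default 15 min,
#' the interval at which CHO migration assays are scored), sums the segment
#' lengths and divides by the elapsed time. Because path length can only
#' shrink under coarser sampling (triangle inequality), the raw-frame speed
#' is also returned as an attribute.
#'
#' @param traj a `cell_trajectory` from [simulate_cell], or a data frame /
#'   matrix with columns `t`, `nuc_x`, `nuc_y`, `nuc_z`
#' @param sampling_interval resampling interval, s (default 900)
#' @return speed in nm/s (attribute `raw_nm_s`: speed at full frame rate)
#' @export
migration_speed <- function(traj, sampling_interval = 900) {
  fr <- if (inherits(traj, "cell_trajectory")) traj$frames else
    as.data.frame(traj)
  stopifnot(all(c("t", "nuc_x", "nuc_y", "nuc_z") %in% names(fr)))
  tmax <- max(fr$t)
  if (tmax < sampling_interval) {
    stop("track shorter than one sampling interval")
  }
  ts <- seq(0, tmax, by = sampling_interval)
  px <- stats::approx(fr$t, fr$nuc_x, xout = ts)$y
  py <- stats::approx(fr$t, fr$nuc_y, xout = ts)$y
  pz <- stats::approx(fr$t, fr$nuc_z, xout = ts)$y
  path <- sum(sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2))
  out <- path / (max(ts) - min(ts))
  raw <- sum(sqrt(diff(fr$nuc_x)^2 + diff(fr$nuc_y)^2 +
                    diff(fr$nuc_z)^2)) / tmax
  attr(out, "raw_nm_s") <- raw
  out
}

#' Traction stress from a focal-adhesion force table
#'
#' Sum of the magnitudes of the in-plane (tangential) FA force components
#' divided by the ventral contact area where FAs are formed, in Pa
#' (1 pN/um^2 = 1 Pa).
#'
#' @param tangential_pN per-FA tangential force magnitudes, pN
#' @param contact_area_um2 total contact area of the FA-bearing nodes, um^2
#' @return stress in Pa
#' @export
traction_stress <- function(tangential_pN, contact_area_um2) {
  if (length(tangential_pN) == 0 || all(tangential_pN == 0)) {
    if (sum(tangential_pN) == 0 && contact_area_um2 <= 0) return(0)
  }
  if (contact_area_um2 <= 0) stop("FAs exist but contact area is zero")
  sum(abs(tangential_pN)) / contact_area_um2
}

#' Leading- vs trailing-edge stress-fiber lifetime statistics
#'
#' Pools the completed motor-phase durations of nucleus-connected stress
#' fibers, classified leading/trailing at fiber birth by the sign of
#' (FA position - nucleus center) dot polarity (ties count as leading), and
#' returns per-group means, standard errors and counts.
#'
#' @param sf_log data frame with columns `motor_duration_s`, `kind`
#'   (0 = nuclear) and `leading` (1/0), as produced by [simulate_cell]
#' @param kinds fiber kinds to pool (default nuclear only, i.e. kind 0)
#' @return list `leading`, `trailing` (each mean, se, n) and `n_total`
#' @export
sf_lifetime_stats <- function(sf_log, kinds = 0) {
  sl <- sf_log[sf_log$kind %in% kinds, , drop = FALSE]
  if (nrow(sl) < 2) stop("need at least 2 completed motor phases")
  grp <- function(d) {
    list(mean = mean(d), se = stats::sd(d) / sqrt(length(d)),
         n = length(d))
  }
  lead <- sl$motor_duration_s[sl$leading == 1]
  trail <- sl$motor_duration_s[sl$leading == 0]
  list(leading = grp(lead), trailing = grp(trail), n_total = nrow(sl))
}

#' Migration speed versus ligand density experiment
#'
#' Runs the planar migration scenario for each density x replicate with
#' distinct seeds and tabulates the time-averaged speed. The biphasic
#' adhesion-migration relationship makes the mean speed peak at an
#' intermediate density.
#'
#' @param densities ligand surface densities, molecules/um^2 (default the
#'   five assayed values 19.4, 192, 568, 1140, 1522)
#' @param replicates runs per density (default 3)
#' @param duration simulated time per run, s (default 3600)
#' @param seed base seed; run (i, j) uses seed + 1000 i + j
#' @param cfg base [sim_config] (density, duration and seed are overridden)
#' @param sampling_interval speed resampling interval, s (default 900)
#' @param verbose print progress
#' @return data frame: density, mean speed, SE, replicate count; attribute
#'   `argmax_density` gives the density with the highest mean speed
#' @export
speed_vs_density_experiment <- function(densities = c(19.4, 192, 568, 1140,
                                                      1522),
                                        replicates = 3, duration = 3600,
                                        seed = 1, cfg = sim_config(),
                                        sampling_interval = 900,
                                        verbose = FALSE) {
  stopifnot(replicates >= 1)
  rows <- lapply(seq_along(densities), function(i) {
    sp <- vapply(seq_len(replicates), function(j) {
      cfg$c_L <- densities[i]
      cfg$duration <- duration
      cfg$seed <- seed + 1000L * i + j
      tr <- simulate_cell(cfg, "migration")
      s <- as.numeric(migration_speed(tr, sampling_interval))
      if (verbose) {
        message(sprintf("c_L = %g rep %d: %.3f nm/s", densities[i], j, s))
      }
      s
    }, numeric(1))
    data.frame(density = densities[i], mean_speed_nm_s = mean(sp),
               se_nm_s = if (replicates > 1) stats::sd(sp) / sqrt(replicates)
                         else NA_real_,
               n = replicates)
  })
  out <- do.call(rbind, rows)
  attr(out, "argmax_density") <- out$density[which.max(out$mean_speed_nm_s)]
  out
}

#' Write the per-frame log and stress-fiber event log as CSV
#'
#' @param traj a `cell_trajectory`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_trajectory_csv <- function(traj, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "frames.csv")
  p2 <- file.path(dir, "sf_log.csv")
  utils::write.csv(traj$frames, p1, row.names = FALSE)
  utils::write.csv(traj$sf_log, p2, row.names = FALSE)
  p3 <- file.path(dir, "fa_table.csv")
  utils::write.csv(data.frame(node = seq_along(traj$n_b), n_b = traj$n_b,
                              fa_force_pN = traj$fa_force_pN,
                              fa_tangential_pN = traj$fa_tangential_pN),
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
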