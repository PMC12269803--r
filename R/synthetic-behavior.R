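#' Simulate an open-field arena trajectory
#'
#' A reflected Gaussian random walk in a square arena. At `wall_bias = 0` the
#' stationary occupancy is uniform over the arena (reflected Brownian
#' motion); `wall_bias > 0` adds a per-frame drift of that many centimetres
#' toward the nearest wall, producing thigmotaxis-like occupancy. Steps are
#' optionally capped at `speed_cap_cm_s`; positions always stay inside
#' `[0, arena_side_cm]^2`. The walk starts from a uniform draw, i.e. in the
#' stationary regime for the unbiased walk.
#'
#' `step_sd_cm` sets the per-axis Gaussian step SD per frame. The default
#' (0.35 cm at 30 fps, ~10 cm/s RMS speed) is mouse-like; large values give
#' a fast-mixing walk whose frames are nearly independent draws from the
#' stationary distribution, useful for occupancy calibration.
#'
#' @param arena_side_cm arena side length (cm); default 63.5.
#' @param fps frames per second; default 30.
#' @param duration_s session duration (s).
#' @param wall_bias drift toward the nearest wall, cm/frame (>= 0).
#' @param seed integer seed.
#' @param step_sd_cm per-axis step SD, cm/frame.
#' @param speed_cap_cm_s cap on instantaneous speed (default `Inf`).
#' @return A `trajectory`: data frame `(t, x, y)` with attributes `fps` and
#'   `arena_side_cm`.
#' @export
simulate_trajectory <- function(arena_side_cm = 63.5, fps = 30, duration_s,
                                wall_bias = 0, seed = 1L,
                                step_sd_cm = 0.35, speed_cap_cm_s = Inf) {
  stopifnot(arena_side_cm > 0, fps > 0, duration_s > 0, wall_bias >= 0,
            step_sd_cm > 0)
  n <- round(fps * duration_s)
  L <- arena_side_cm
  cap <- speed_cap_cm_s / fps
  pos <- with_seed(seed, {
    x <- numeric(n)
    y <- numeric(n)
    x[1L] <- stats::runif(1L, 0, L)
    y[1L] <- stats::runif(1L, 0, L)
    sx <- stats::rnorm(n, 0, step_sd_cm)
    sy <- stats::rnorm(n, 0, step_sd_cm)
    for (i in seq_len(n - 1L)) {
      dx <- sx[i]
      dy <- sy[i]
      if (wall_bias > 0) {
        # drift toward the nearest of the four walls
        dists <- c(x[i], L - x[i], y[i], L - y[i])
        w <- which.min(dists)
        if (w == 1L) dx <- dx - wall_bias
        else if (w == 2L) dx <- dx + wall_bias
        else if (w == 3L) dy <- dy - wall_bias
        else dy <- dy + wall_bias
      }
      len <- sqrt(dx^2 + dy^2)
      if (is.finite(cap) && len > cap) {
        dx <- dx * cap / len
        dy <- dy * cap / len
      }
      x[i + 1L] <- reflect_into(x[i] + dx, L)
      y[i + 1L] <- reflect_into(y[i] + dy, L)
    }
    data.frame(t = (seq_len(n) - 1L) / fps, x = x, y = y)
  })
  trajectory(pos, fps = fps, arena_side_cm = arena_side_cm)
}

# fold a coordinate back into [0, L] by reflection at the walls
reflect_into <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Construct a trajectory object
#'
#' @param frames data frame with columns `t` (s), `x`, `y` (cm).
#' @param fps frame rate (Hz).
#' @param arena_side_cm arena side length (cm).
#' @return A `trajectory` data frame with `fps` and `arena_side_cm`
#'   attributes.
#' @export
trajectory <- function(frames, fps, arena_side_cm) {
  stopifnot(is.data.frame(frames), all(c("t", "x", "y") %in% names(frames)),
            fps > 0, arena_side_cm > 0)
  ok <- stats::complete.cases(frames[, c("x", "y")])
  if (any(frames$x[ok] < 0 | frames$x[ok] > arena_side_cm |
            frames$y[ok] < 0 | frames$y[ok] > arena_side_cm)) {
    stop("positions outside the arena")
  }
  structure(frames, fps = fps, arena_side_cm = arena_side_cm,
            class = c("trajectory", "data.frame"))
}

#' Simulate accelerating-rotarod latencies
#'
#' Per-trial latency to fall: `baseline + learning * (day - 1) + group_offset
#' + noise`, clipped to the 0-300 s trial window of the accelerating
#' protocol. One call generates one experimental group; bind several calls
#' for a cohort design.
#'
#' @param n_mice,n_days,n_trials design counts (all >= 1); defaults 3 days x
#'   3 trials.
#' @param baseline_s day-1 mean latency (s).
#' @param learning_s_per_day latency gained per day (s).
#' @param group_offset_s additive group effect (s).
#' @param noise_sd trial-level Gaussian noise SD (s).
#' @param seed integer seed.
#' @param group group label attached to every row.
#' @param mouse_prefix prefix for mouse ids.
#' @return Data frame `(mouse, group, day, trial, latency)` with one row per
#'   trial; latencies in `[0, 300]`.
#' @export
simulate_rotarod <- function(n_mice, n_days = 3L, n_trials = 3L,
                             baseline_s = 100, learning_s_per_day = 20,
                             group_offset_s = 0, noise_sd = 10, seed = 1L,
                             group = "A", mouse_prefix = group) {
  stopifnot(n_mice >= 1L, n_days >= 1L, n_trials >= 1L, noise_sd >= 0)
  grid <- expand.grid(trial = seq_len(n_trials), day = seq_len(n_days),
                      mouse = paste0(mouse_prefix, seq_len(n_mice)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lat <- with_seed(seed, {
    baseline_s + learning_s_per_day * (grid$day - 1) + group_offset_s +
      stats::rnorm(nrow(grid), 0, noise_sd)
  })
  data.frame(mouse = grid$mouse, group = group, day = grid$day,
             trial = grid$trial, latency = clamp(lat, 0, 300))
}

#' Simulate a grouped assay table (analyte + total protein)
#'
#' Draws per-sample analyte concentrations around group means and a total
#' protein concentration per sample; the normalized value is analyte divided
#' by protein ([normalize_assay()]). Nonpositive protein draws are redrawn so
#' every generated sample satisfies the normalization precondition.
#'
#' @param group_means,group_sds,n_per_group equal-length vectors of group
#'   analyte means, SDs (>= 0) and sample counts (>= 1).
#' @param protein_mean,protein_sd total-protein distribution (default mean 1,
#'   SD 0: protein identically 1, normalized = raw).
#' @param seed integer seed.
#' @param group_labels optional group names; default G1, G2, ...
#' @return Data frame `(sample, group, analyte, protein, normalized)`.
#' @export
simulate_assay <- function(group_means, group_sds, n_per_group,
                           protein_mean = 1, protein_sd = 0, seed = 1L,
                           group_labels = NULL) {
  k <- length(group_means)
  stopifnot(length(group_sds) == k, length(n_per_group) == k,
            all(group_sds >= 0), all(n_per_group >= 1), protein_mean > 0,
            protein_sd >= 0)
  if (is.null(group_labels)) group_labels <- paste0("G", seq_len(k))
  stopifnot(length(group_labels) == k)
  n_tot <- sum(n_per_group)
  with_seed(seed, {
    grp <- rep(group_labels, n_per_group)
    mu <- rep(group_means, n_per_group)
    sd <- rep(group_sds, n_per_group)
    analyte <- stats::rnorm(n_tot, mu, sd)
    protein <- stats::rnorm(n_tot, protein_mean, protein_sd)
    for (g in seq_len(50L)) {            # redraw nonpositive protein values
      bad <- protein <= 0
      if (!any(bad)) break
      protein[bad] <- stats::rnorm(sum(bad), protein_mean, protein_sd)
    }
    protein <- pmax(protein, .Machine$double.eps)
    data.frame(sample = paste0("S", seq_len(n_tot)), group = grp,
               analyte = analyte, protein = protein,
               normalized = normalize_assay(analyte, protein))
  })
}
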