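#' Open-field zone geometry
#'
#' Defines the arena zones used for thigmotaxis analysis: a concentric
#' center rectangle whose side is `center_factor` times the arena side
#' (default 0.7, area fraction 0.49), and four corner triangles each spanned
#' by a corner and the two points a fraction `corner_factor` (default 0.3)
#' along the adjacent walls (total corner area fraction `2 * f^2` = 0.18).
#' Everything else is `rest`. With non-default factors the corner triangles
#' can overlap the center rectangle; points are assigned with precedence
#' corner > center > rest, so every point belongs to exactly one zone.
#'
#' @param arena_side_cm arena side length (cm).
#' @param center_factor center-rectangle side scale (default 0.7).
#' @param corner_factor wall fraction spanned by each corner triangle
#'   (default 0.3).
#' @return A `zone_geometry` object.
#' @export
zone_geometry <- function(arena_side_cm, center_factor = 0.7,
                          corner_factor = 0.3) {
  stopifnot(arena_side_cm > 0, center_factor > 0, center_factor <= 1,
            corner_factor >= 0, corner_factor <= 1)
  structure(list(arena_side_cm = arena_side_cm, center_factor = center_factor,
                 corner_factor = corner_factor),
            class = "zone_geometry")
}

#' Classify arena positions into zones
#'
#' @param geom a [zone_geometry()].
#' @param x,y numeric position vectors (cm).
#' @return Character vector in `{"corner", "center", "rest"}`.
#' @export
classify_points <- function(geom, x, y) {
  stopifnot(inherits(geom, "zone_geometry"))
  L <- geom$arena_side_cm
  fL <- geom$corner_factor * L
  half <- geom$center_factor * L / 2
  corner <- (x + y <= fL) | ((L - x) + y <= fL) |
    (x + (L - y) <= fL) | ((L - x) + (L - y) <= fL)
  center <- abs(x - L / 2) <= half & abs(y - L / 2) <= half
  ifelse(corner, "corner", ifelse(center, "center", "rest"))
}

#' Per-zone time fractions for an open-field session
#'
#' Assigns every frame in the first `window_s` seconds to exactly one zone
#' (corner > center > rest precedence) and returns the time fraction per
#' zone; fractions sum to 1. Frames with missing coordinates (tracking
#' dropouts) are excluded from numerator and denominator with a message. A
#' trajectory shorter than the window triggers a truncation warning
#' reporting the window actually used.
#'
#' @param traj a [trajectory()].
#' @param geom a [zone_geometry()]; defaults to the trajectory's arena with
#'   standard factors.
#' @param window_s analysis window from session start (s); default 300
#'   (first 5 min).
#' @return List with `fractions` (named numeric: center, corner, rest),
#'   `n_frames`, `n_dropped` and `window_used_s`.
#' @export
classify_zones <- function(traj, geom = NULL, window_s = 300) {
  stopifnot(inherits(traj, "trajectory"), window_s > 0)
  if (is.null(geom)) geom <- zone_geometry(attr(traj, "arena_side_cm"))
  span <- max(traj$t) - min(traj$t)
  window_used <- window_s
  if (span < window_s) {
    window_used <- span
    warning("trajectory covers only ", format(span, digits = 4),
            " s; using truncated window")
  }
  sel <- traj$t <= min(traj$t) + window_used + 1e-9
  x <- traj$x[sel]
  y <- traj$y[sel]
  ok <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " frame(s) with missing coordinates excluded")
  }
  zone <- classify_points(geom, x[ok], y[ok])
  counts <- c(center = sum(zone == "center"), corner = sum(zone == "corner"),
              rest = sum(zone == "rest"))
  list(fractions = counts / sum(counts), n_frames = sum(ok),
       n_dropped = n_dropped, window_used_s = window_used)
}

#' Open-field kinematics: distance traveled and mean velocity
#'
#' Distance is the sum of Euclidean steps between consecutive tracked
#' frames within the window; mean velocity is distance divided by elapsed
#' time. Frames with missing coordinates are excluded.
#'
#' @param traj a [trajectory()].
#' @param window_s analysis window from session start (s); default 300.
#' @return List with `distance_cm` and `mean_velocity_cm_s`.
#' @export
kinematics <- function(traj, window_s = 300) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- traj$t <= min(traj$t) + window_s + 1e-9
  d <- traj[sel, ]
  d <- d[!is.na(d$x) & !is.na(d$y), ]
  if (nrow(d) < 2L) stop("need at least 2 tracked frames in the window")
  dist <- sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
  elapsed <- max(d$t) - min(d$t)
  list(distance_cm = dist, mean_velocity_cm_s = dist / elapsed)
}

#' Summarize rotarod latencies per mouse and day
#'
#' The day-level summary is the mean latency across that day's trials — the
#' quantity used for statistical analysis in the accelerating-rotarod
#' protocol; the overall summary averages each mouse's day means. A mouse
#' missing a day simply has no row for it, and `n_days` in the overall table
#' flags incomplete mice; nothing is imputed.
#'
#' @param trials data frame `(mouse, day, trial, latency)` (a `group` column
#'   is carried through if present); latencies must lie in `[0, 300]`.
#' @return List with `by_day` (mouse x day mean latency, `n_trials`) and
#'   `overall` (per-mouse mean of day means, `n_days`).
#' @export
rotarod_summary <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("mouse", "day", "latency") %in% names(trials)))
  if (any(trials$latency < 0 | trials$latency > 300)) {
    stop("latencies must lie in [0, 300] s")
  }
  keys <- c("mouse", if ("group" %in% names(trials)) "group", "day")
  by_day <- stats::aggregate(latency ~ ., data = trials[, c(keys, "latency")],
                             FUN = mean)
  names(by_day)[names(by_day) == "latency"] <- "mean_latency"
  n_tr <- stats::aggregate(trials$latency, by = trials[, keys, drop = FALSE],
                           FUN = length)
  by_day$n_trials <- n_tr$x[match(
    do.call(paste, by_day[keys]), do.call(paste, n_tr[keys]))]
  keys2 <- setdiff(keys, "day")
  overall <- stats::aggregate(by_day$mean_latency,
                              by = by_day[, keys2, drop = FALSE], FUN = mean)
  names(overall)[names(overall) == "x"] <- "overall_mean"
  nd <- stats::aggregate(by_day$day, by = by_day[, keys2, drop = FALSE],
                         FUN = length)
  overall$n_days <- nd$x[match(
    do.call(paste, overall[keys2]), do.call(paste, nd[keys2]))]
  by_day <- by_day[order(by_day$mouse, by_day$day), ]
  rownames(by_day) <- rownames(overall) <- NULL
  list(by_day = by_day, overall = overall)
}

#' Plot a trajectory over the arena zone geometry
#'
#' Zone-overlay figure: center rectangle, corner triangles and the path of
#' the animal, color-coded by zone. Requires ggplot2.
#'
#' @param traj a [trajectory()].
#' @param geom a [zone_geometry()]; defaults from the trajectory.
#' @param window_s window to plot (default 300 s).
#' @return A ggplot object.
#' @export
plot_zones <- function(traj, geom = NULL, window_s = 300) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  if (is.null(geom)) geom <- zone_geometry(attr(traj, "arena_side_cm"))
  L <- geom$arena_side_cm
  fL <- geom$corner_factor * L
  half <- geom$center_factor * L / 2
  sel <- traj$t <= min(traj$t) + window_s + 1e-9
  d <- traj[sel & !is.na(traj$x) & !is.na(traj$y), ]
  d$zone <- classify_points(geom, d$x, d$y)
  tri <- do.call(rbind, list(
    data.frame(id = 1, x = c(0, fL, 0), y = c(0, 0, fL)),
    data.frame(id = 2, x = c(L, L - fL, L), y = c(0, 0, fL)),
    data.frame(id = 3, x = c(0, fL, 0), y = c(L, L, L - fL)),
    data.frame(id = 4, x = c(L, L - fL, L), y = c(L, L, L - fL))
  ))
  ggplot2::ggplot() +
    ggplot2::annotate("rect", xmin = 0, xmax = L, ymin = 0, ymax = L,
                      fill = NA, colour = "black") +
    ggplot2::annotate("rect", xmin = L / 2 - half, xmax = L / 2 + half,
                      ymin = L / 2 - half, ymax = L / 2 + half,
                      fill = "grey85", colour = "grey40") +
    ggplot2::geom_polygon(data = tri,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$id),
                          fill = "grey70", colour = "grey40") +
    ggplot2::geom_path(data = d,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey50", linewidth = 0.2) +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$zone), size = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = "zone")
}
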