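#' Raw gaze trajectory
#'
#' A uniformly sampled gaze record: time, screen position and pupil
#' diameter (relative to the calibration baseline, so 0 means the
#' calibration diameter). Optional metadata carry the symbol label, the
#' disability level and a writer/alphabet identifier for labeled
#' exemplars.
#'
#' @param t strictly increasing sample times in seconds, nominally evenly
#'   spaced (checked within 1% of the median interval).
#' @param x,y gaze position in pixels (mathematical convention: y grows
#'   upward; flip screen coordinates at ingestion, see [read_trajectory()]).
#' @param d pupil diameter relative to calibration.
#' @param label,disability,writer optional exemplar metadata.
#' @return A `data.frame` of class `ew_trajectory` with columns
#'   `t, x, y, d` and metadata attributes.
#' @examples
#' tr <- raw_trajectory(t = (0:74) / 75, x = 0:74, y = rep(0, 75))
#' nrow(tr)
#' @export
raw_trajectory <- function(t, x, y, d = rep(0, length(t)),
                           label = NULL, disability = NULL, writer = NULL) {
  n <- length(t)
  if (n < 2) stop("raw_trajectory(): need at least 2 samples", call. = FALSE)
  if (length(x) != n || length(y) != n || length(d) != n)
    stop("raw_trajectory(): t, x, y, d must have equal length", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(x)) ||
      !all(is.finite(y)) || !all(is.finite(d)))
    stop("raw_trajectory(): non-finite values", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("raw_trajectory(): t must be strictly increasing", call. = FALSE)
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
    stop("raw_trajectory(): sampling interval not uniform within 1%",
         call. = FALSE)
  out <- data.frame(t = t, x = x, y = y, d = d)
  attr(out, "label") <- label
  attr(out, "disability") <- disability
  attr(out, "writer") <- writer
  class(out) <- c("ew_trajectory", "data.frame")
  out
}

# Reflect an out-of-range index back into 1..k (mirror about the edge
# samples, no edge duplication).
reflect_index <- function(i, k) {
  if (k == 1) return(rep(1L, length(i)))
  period <- 2L * (k - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= k, period - j, j)
  j + 1L
}

#' Binomial smoothing filter
#'
#' Convolves a series with the normalized binomial kernel
#' `choose(order, 0:order) / 2^order` (a cheap discrete approximation of a
#' Gaussian). Boundaries are handled by reflecting the series about its
#' end samples, so the filter has DC gain exactly 1 and leaves constants
#' untouched; output length equals input length.
#'
#' @param series numeric vector.
#' @param order non-negative integer filter order; `order = 0` is the
#'   identity.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' binomial_smooth(c(5, 5, 5, 5), 20)  # unchanged
#' @export
binomial_smooth <- function(series, order) {
  if (length(series) < 1) stop("binomial_smooth(): empty series", call. = FALSE)
  order <- as.integer(order)
  if (order < 0) stop("binomial_smooth(): order must be >= 0", call. = FALSE)
  if (order == 0 || length(series) == 1) return(series)
  kern <- choose(order, 0:order) / 2^order
  offs <- 0:order - order %/% 2L
  n <- length(series)
  out <- numeric(n)
  idx <- seq_len(n)
  for (j in seq_along(kern))
    out <- out + kern[j] * series[reflect_index(idx + offs[j], n)]
  out
}

#' Finite-difference velocity
#'
#' Per-sample derivative of a uniformly sampled signal: central
#' differences at interior samples, one-sided differences at the two ends.
#' Exact for affine signals everywhere and for quadratics at interior
#' samples.
#'
#' @param positions numeric vector (>= 2 samples).
#' @param dt sampling interval (> 0).
#' @return Numeric vector of the same length.
#' @examples
#' finite_difference_velocity(3 * (0:10) * 0.1, dt = 0.1)  # all 3
#' @export
finite_difference_velocity <- function(positions, dt) {
  n <- length(positions)
  if (n < 2)
    stop("finite_difference_velocity(): need >= 2 samples", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("finite_difference_velocity(): dt must be > 0", call. = FALSE)
  v <- numeric(n)
  v[1] <- (positions[2] - positions[1]) / dt
  v[n] <- (positions[n] - positions[n - 1]) / dt
  if (n > 2)
    v[2:(n - 1)] <- (positions[3:n] - positions[1:(n - 2)]) / (2 * dt)
  v
}

#' Kinematic trajectory
#'
#' Applies the deterministic smoothing stage to a raw gaze record:
#' positions are smoothed with the binomial filter, velocities are
#' computed by finite differences and smoothed again (both positions and
#' velocities are filtered), and the per-sample acceleration magnitude is
#' derived from the smoothed velocities in px/sample^2 — the unit in which
#' the saccade-trimming threshold is expressed.
#'
#' @param traj an [raw_trajectory()].
#' @param config an [ew_config()].
#' @return Object of class `ew_kinematic`: list with `t`, `x`, `y`
#'   (smoothed positions, px), `vx`, `vy` (smoothed velocities, px/s),
#'   `accel` (px/sample^2), `dt`, `pupil`, and the metadata of the input.
#' @export
kinematics <- function(traj, config = ew_config()) {
  config <- as_ew_config(config)
  stopifnot(inherits(traj, "ew_trajectory") || is.data.frame(traj))
  dt <- stats::median(diff(traj$t))
  ord <- config$binomial_order
  x <- binomial_smooth(traj$x, ord)
  y <- binomial_smooth(traj$y, ord)
  vx <- binomial_smooth(finite_difference_velocity(x, dt), ord)
  vy <- binomial_smooth(finite_difference_velocity(y, dt), ord)
  # acceleration magnitude in px/sample^2: derivative (per sample) of the
  # per-sample velocity vector
  ax <- finite_difference_velocity(vx * dt, 1)
  ay <- finite_difference_velocity(vy * dt, 1)
  structure(
    list(t = traj$t, x = x, y = y, vx = vx, vy = vy,
         accel = sqrt(ax^2 + ay^2), dt = dt, pupil = traj$d,
         label = attr(traj, "label"), disability = attr(traj, "disability"),
         writer = attr(traj, "writer")),
    class = "ew_kinematic")
}

#' @export
print.ew_kinematic <- function(x, ...) {
  cat(sprintf("<ew_kinematic> %d samples, dt = %.4g s%s\n",
              length(x$t), x$dt,
              if (!is.null(x$label)) paste0(", label '", x$label, "'") else ""))
  invisible(x)
}

subset_kinematic <- function(traj, keep) {
  traj$t <- traj$t[keep]; traj$x <- traj$x[keep]; traj$y <- traj$y[keep]
  traj$vx <- traj$vx[keep]; traj$vy <- traj$vy[keep]
  traj$accel <- traj$accel[keep]; traj$pupil <- traj$pupil[keep]
  traj
}

#' Remove intrusive saccades at trajectory ends
#'
#' Eye-written trajectories begin with a "burn-in" of movement initiation
#' and end just before a blink; both portions are prone to small ballistic
#' saccades. Within the first `head` samples, if any sample's acceleration
#' exceeds `threshold`, all samples up to the last such sample are
#' deleted; symmetrically, within the last `tail` samples, everything from
#' the first offending sample onward is deleted. If trimming would leave
#' fewer than 2 samples the trajectory is returned unchanged with a
#' degenerate-trajectory warning.
#'
#' @param traj an `ew_kinematic` (see [kinematics()]).
#' @param threshold acceleration threshold, px/sample^2.
#' @param head,tail number of leading/trailing samples inspected.
#' @return Trimmed `ew_kinematic`.
#' @export
trim_intrusive_saccades <- function(traj, threshold = 0.4,
                                    head = 30L, tail = 5L) {
  stopifnot(inherits(traj, "ew_kinematic"))
  n <- length(traj$t)
  if (n < 1) stop("trim_intrusive_saccades(): empty trajectory", call. = FALSE)
  first <- 1L
  hw <- which(traj$accel[seq_len(min(head, n))] > threshold)
  if (length(hw)) first <- max(hw) + 1L
  last <- n
  tail_idx <- seq.int(max(1L, n - tail + 1L), n)
  tw <- tail_idx[traj$accel[tail_idx] > threshold]
  if (length(tw)) last <- min(tw) - 1L
  if (last - first + 1L < 2L) {
    warning(warningCondition(
      "trim_intrusive_saccades(): trimming would leave < 2 samples; trajectory returned untrimmed",
      class = "eyewrite_degenerate_trajectory"))
    return(traj)
  }
  if (first == 1L && last == n) return(traj)
  subset_kinematic(traj, first:last)
}

#' Extract via-points from a kinematic trajectory
#'
#' Via-points are the samples where the x- or y-velocity crosses zero
#' (trajectory extrema), plus the first and last samples. On the discrete
#' signal a crossing between samples i and i+1 is attributed to the sample
#' with the smaller absolute velocity in the crossing dimension. A
#' geometric constraint discards interior candidates whose x *and* y
#' distances to the previously kept via-point are both below `min_sep`
#' (suppressing spurious candidates along plateaus); the final sample is
#' always kept. At most `max_count` via-points are retained,
#' earliest-first. Each via-point carries the relative displacement since
#' the previously kept via-point (`dx`, `dy`; the first gets (0, 0)) and
#' the instantaneous velocities.
#'
#' @param traj an `ew_kinematic` (smoothed, trimmed).
#' @param max_count maximum number of via-points (15).
#' @param min_sep minimum separation in px (2).
#' @return `data.frame` of class `ew_viapoints` with columns
#'   `k, dx, dy, vx, vy, sample` (sample index in `traj`).
#' @export
extract_via_points <- function(traj, max_count = 15L, min_sep = 2) {
  stopifnot(inherits(traj, "ew_kinematic"))
  n <- length(traj$t)
  if (n < 2) stop("extract_via_points(): need >= 2 samples", call. = FALSE)

  crossing_candidates <- function(v) {
    if (n < 2) return(integer(0))
    s <- sign(v)
    idx <- which(s[-n] != s[-1] | s[-n] == 0)
    if (!length(idx)) return(which(s == 0))
    cand <- ifelse(abs(v[idx]) <= abs(v[idx + 1L]), idx, idx + 1L)
    unique(c(cand, which(s == 0)))
  }
  cand <- sort(unique(c(crossing_candidates(traj$vx),
                        crossing_candidates(traj$vy))))
  cand <- setdiff(cand, c(1L, n))
  kept <- 1L
  for (i in cand) {
    prev <- kept[length(kept)]
    if (abs(traj$x[i] - traj$x[prev]) < min_sep &&
        abs(traj$y[i] - traj$y[prev]) < min_sep) next
    kept <- c(kept, i)
  }
  kept <- c(kept, n)
  if (length(kept) > max_count) kept <- kept[seq_len(max_count)]
  xk <- traj$x[kept]; yk <- traj$y[kept]
  out <- data.frame(
    k = seq_along(kept),
    dx = c(0, diff(xk)), dy = c(0, diff(yk)),
    vx = traj$vx[kept], vy = traj$vy[kept],
    sample = kept)
  class(out) <- c("ew_viapoints", "data.frame")
  out
}

#' Auxiliary trajectory features
#'
#' Computed once a trajectory is complete: its width `sx` and height `sy`
#' (bounding box, px), the spectral energy `a` of the velocity signal
#' above the frequency split `f0` (the high-frequency component left by
#' undetected saccades and ocular microtremor), and the mean `mup` and
#' standard deviation `sigmap` of the pupil-diameter series.
#'
#' The spectral energy sums the discrete power spectra of the x- and
#' y-velocities over all frequency bins strictly above `f0`, with the
#' Parseval-friendly normalization `sum(|fft(v)|^2) / n^2 = mean(v^2)`:
#' a pure sinusoidal velocity of amplitude `a0` above the split
#' contributes `a0^2 / 2` per axis. Units: (px/s)^2.
#'
#' @param traj an `ew_kinematic`.
#' @param pupil pupil-diameter series (defaults to the trajectory's own).
#' @param f0 frequency split, Hz (2.6).
#' @param sample_rate sampling rate, Hz; must exceed `2 * f0` so that a
#'   band above the split exists.
#' @return Object of class `ew_aux`: list with `sx`, `sy`, `a`, `mup`,
#'   `sigmap`.
#' @export
compute_aux_features <- function(traj, pupil = traj$pupil, f0 = 2.6,
                                 sample_rate = 1 / traj$dt) {
  stopifnot(inherits(traj, "ew_kinematic"))
  if (sample_rate <= 2 * f0)
    stop("compute_aux_features(): sample_rate must exceed 2 * f0",
         call. = FALSE)
  n <- length(traj$t)
  freqs <- (seq_len(n) - 1) / n * sample_rate
  freqs <- pmin(freqs, sample_rate - freqs)  # two-sided -> |f|
  band <- freqs > f0
  spec_energy <- function(v) sum(Mod(stats::fft(v))[band]^2) / n^2
  m <- mean(pupil)
  structure(
    list(sx = max(traj$x) - min(traj$x),
         sy = max(traj$y) - min(traj$y),
         a = spec_energy(traj$vx) + spec_energy(traj$vy),
         mup = m,
         sigmap = sqrt(mean((pupil - m)^2))),
    class = "ew_aux")
}

#' @export
print.ew_aux <- function(x, ...) {
  cat(sprintf("<ew_aux> sx=%.1f sy=%.1f a=%.2f mup=%.3f sigmap=%.3f\n",
              x$sx, x$sy, x$a, x$mup, x$sigmap))
  invisible(x)
}

#' Full deterministic preprocessing of one trajectory
#'
#' Smooth, trim, extract via-points and auxiliary features: the complete
#' algorithmic front end, turning a raw gaze record into the model's
#' continuous feature set.
#'
#' @param traj an [raw_trajectory()].
#' @param config an [ew_config()].
#' @return Object of class `ew_features`: list with `via`
#'   (`ew_viapoints`), `aux` (`ew_aux`), `label`, `disability`, `writer`.
#' @examples
#' tmpl <- letter_templates()[[1]]
#' tr <- generate_trajectory(tmpl, gen_config(), seed = 1)
#' f <- process_trajectory(tr)
#' nrow(f$via)
#' @export
process_trajectory <- function(traj, config = ew_config()) {
  config <- as_ew_config(config)
  kin <- kinematics(traj, config)
  kin <- trim_intrusive_saccades(kin, threshold = config$accel_threshold,
                                 head = config$trim_head,
                                 tail = config$trim_tail)
  via <- extract_via_points(kin, max_count = config$max_via_points,
                            min_sep = config$min_sep_px)
  aux <- compute_aux_features(kin, f0 = config$f0_hz,
                              sample_rate = config$sample_rate_hz)
  structure(
    list(via = via, aux = aux, label = kin$label,
         disability = kin$disability, writer = kin$writer),
    class = "ew_features")
}

#' @export
print.ew_features <- function(x, ...) {
  cat(sprintf("<ew_features> %d via-points%s%s\n", nrow(x$via),
              if (!is.null(x$label)) paste0(", label '", x$label, "'") else "",
              if (!is.null(x$disability)) paste0(", H=", x$disability) else ""))
  invisible(x)
}
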