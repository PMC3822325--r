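# Seedable generator of eye-writing-like trajectories: stylized cursive
# strokes traced at smooth-pursuit speeds, contaminated with pursuit
# noise, ocular microtremor, movement-initiation saccades and pupil
# drift, with a three-level motor-impairment manipulation.

#' Generator configuration
#'
#' Defaults emulate a cooperative healthy writer on a 75 Hz tracker:
#' letters fit a 100 x 100 px box and are traced at roughly 150-250 px/s
#' (so scaled velocities fill the -10..10 domain); pursuit noise is
#' white with SD 1 px; a faint 0.3 px ocular-microtremor component sits
#' at 6 Hz (above the 2.6 Hz split); one trajectory in four starts with a
#' 25 px initiation saccade (exercising the trimming stage); the pupil
#' series is a slow random walk around +0.1 of the calibration diameter.
#' The impairment manipulation scales trajectories by 4/5 (level 2) or
#' 1/2 (level 3) about their centroid, adds a 6 Hz sinusoid of 2 px
#' (level 2) or 5 px (level 3), shifts the mean pupil diameter by +0.1 /
#' +0.2 and shrinks its variability by x0.7 / x0.4.
#'
#' @param ... named overrides.
#' @return Named list of class `ew_gen_config`.
#' @export
gen_config <- function(...) {
  defaults <- list(
    sample_rate = 75,
    pursuit_noise_sd = 1,
    omt_amplitude = 0.3,
    omt_freq = 6,
    saccade_prob = 0.25,
    saccade_amplitude = 25,
    pupil_baseline = 0.1,
    pupil_drift_sd = 0.02,
    tremor_amplitude = c(0, 2, 5),
    tremor_freq = 6,
    pupil_shift = c(0, 0.1, 0.2),
    pupil_sd_factor = c(1, 0.7, 0.4),
    scale_factor = c(1, 4 / 5, 1 / 2),
    allograph_frac = 0,
    box = 100
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("gen_config(): all overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("gen_config(): unknown key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "ew_gen_config")
}

as_gen_config <- function(config) {
  if (inherits(config, "ew_gen_config")) return(config)
  if (is.null(config)) return(gen_config())
  do.call(gen_config, as.list(config))
}

new_template <- function(symbol, points, duration) {
  stopifnot(nrow(points) >= 3)
  structure(list(symbol = symbol, points = points, duration = duration),
            class = "ew_template")
}

#' @export
print.ew_template <- function(x, ...) {
  cat(sprintf("<ew_template> '%s': %d control points, %.2f s\n",
              x$symbol, nrow(x$points), x$duration))
  invisible(x)
}

base_template_shapes <- function(box = 100) {
  s <- function(n) seq(0, 1, length.out = n)
  u <- box / 100  # shapes are authored in a 100 x 100 box
  shapes <- list(
    loop = {
      a <- 2 * pi * s(13) - pi / 2
      cbind(50 + 40 * cos(a), 50 + 40 * sin(a))
    },
    wave = cbind(100 * s(13), 50 + 35 * sin(2 * pi * 1.5 * s(13))),
    arc = {
      a <- pi * s(9)
      cbind(50 - 45 * cos(a), 15 + 70 * sin(a))
    },
    serp = {
      t <- s(13)
      cbind(50 + 35 * sin(2.5 * pi * t), 100 * (1 - t))
    },
    spiral = {
      t <- s(17)
      r <- 8 + 37 * t
      cbind(50 + r * cos(4 * pi * t), 50 + r * sin(4 * pi * t))
    },
    hook = {
      t <- s(11)
      cbind(30 + 45 * t^2, 95 - 170 * t + 85 * t^2 + 25 * sin(pi * t))
    },
    cup = {
      a <- pi * s(9)
      cbind(50 - 45 * cos(a), 85 - 70 * sin(a))
    },
    vee = {
      t <- s(11)
      cbind(100 * t, 90 - 330 * t * (1 - t))
    },
    tilde = cbind(100 * s(13), 50 + 30 * sin(2 * pi * 2.5 * s(13))),
    curl = {
      t <- s(13)
      a <- 3 * pi * t
      cbind(15 + 70 * t + 18 * cos(a), 50 + 32 * sin(a))
    }
  )
  lapply(shapes, function(p) p * u)
}

fit_to_box <- function(points, box) {
  for (j in 1:2) {
    rng <- range(points[, j])
    span <- max(rng[2] - rng[1], 1e-9)
    points[, j] <- (points[, j] - rng[1]) / span * box
  }
  points
}

path_length <- function(points) sum(sqrt(rowSums(diff(points)^2)))

#' Stylized letter templates
#'
#' Ships ten stylized cursive strokes (loops, waves, arcs, spirals, ...)
#' bounded to a 100 x 100 px box; symbol identity is arbitrary. When more
#' symbols are requested than base shapes exist, additional templates are
#' derived deterministically by rotating base shapes (each batch of ten
#' symbols rotates a further 40 degrees), so any alphabet size is
#' supported. Durations are set so that tracing speed is about 150 px/s,
#' the smooth-pursuit regime the velocity domain is scaled for.
#'
#' @param symbols character vector of symbol names (default: `"s1"` ..
#'   `"s10"`).
#' @param box bounding-box side in px.
#' @return Named list of `ew_template` objects.
#' @export
letter_templates <- function(symbols = paste0("s", 1:10), box = 100) {
  shapes <- base_template_shapes(box)
  out <- vector("list", length(symbols))
  names(out) <- symbols
  for (i in seq_along(symbols)) {
    base <- shapes[[(i - 1L) %% length(shapes) + 1L]]
    rot <- (2 * pi / 9) * ((i - 1L) %/% length(shapes))
    if (rot != 0) {
      ctr <- colMeans(base)
      R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
      base <- sweep(sweep(base, 2, ctr) %*% R, 2, ctr, `+`)
      base <- fit_to_box(base, box)
    }
    duration <- max(path_length(base) / 150, 0.8)
    out[[i]] <- new_template(symbols[i], base, duration)
  }
  out
}

# Alternate geometric form (allograph) of a template: mirrored about the
# vertical axis, same symbol label.
allograph_of <- function(template, box = 100) {
  p <- template$points
  p[, 1] <- box - p[, 1]
  new_template(template$symbol, p, template$duration)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate one eye-writing trajectory
#'
#' Interpolates a cubic spline through the template's control points at
#' the sample rate, then adds white pursuit noise, a sinusoidal
#' ocular-microtremor component with random phase, optionally prepends a
#' high-acceleration initiation saccade, and attaches a random-walk pupil
#' series. Deterministic under a fixed `seed`.
#'
#' @param template an `ew_template`.
#' @param config a [gen_config()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param disability impairment level 1..3 applied via
#'   [simulate_disability()].
#' @param writer optional alphabet/writer id stored as metadata.
#' @return A labeled [raw_trajectory()].
#' @export
generate_trajectory <- function(template, config = gen_config(), seed = NULL,
                                disability = 1L, writer = NULL) {
  config <- as_gen_config(config)
  with_seed(seed, {
    n <- round(template$duration * config$sample_rate) + 1L
    tt <- (seq_len(n) - 1L) / config$sample_rate
    ct <- seq(0, template$duration, length.out = nrow(template$points))
    fx <- stats::splinefun(ct, template$points[, 1], method = "natural")
    fy <- stats::splinefun(ct, template$points[, 2], method = "natural")
    x <- fx(tt); y <- fy(tt)
    if (config$omt_amplitude > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      x <- x + config$omt_amplitude * sin(2 * pi * config$omt_freq * tt + ph[1])
      y <- y + config$omt_amplitude * sin(2 * pi * config$omt_freq * tt + ph[2])
    }
    if (config$pursuit_noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, config$pursuit_noise_sd)
      y <- y + stats::rnorm(n, 0, config$pursuit_noise_sd)
    }
    if (config$saccade_prob > 0 &&
        stats::runif(1) < config$saccade_prob) {
      npre <- 4L
      ang <- stats::runif(1, 0, 2 * pi)
      off <- config$saccade_amplitude * c(cos(ang), sin(ang))
      frac <- rev(seq_len(npre)) / npre
      x <- c(x[1] + off[1] * frac, x)
      y <- c(y[1] + off[2] * frac, y)
      n <- n + npre
      tt <- (seq_len(n) - 1L) / config$sample_rate
    }
    d <- config$pupil_baseline +
      cumsum(stats::rnorm(n, 0, config$pupil_drift_sd))
    traj <- raw_trajectory(tt, x, y, d, label = template$symbol,
                          disability = 1L, writer = writer)
    if (disability != 1L) traj <- simulate_disability(traj, disability, config)
    attr(traj, "writer") <- writer
    traj
  })
}

#' Apply the motor-impairment manipulation
#'
#' Level 1 is the identity. Levels 2 and 3 scale the trajectory spatially
#' about its centroid (factors 4/5 and 1/2), superpose a 6 Hz sinusoidal
#' tremor of small (2 px) or medium (5 px) amplitude with random phase on
#' both axes, shift the mean pupil diameter up (+0.1, +0.2) and shrink
#' the pupil variability (x0.7, x0.4).
#'
#' @param traj a [raw_trajectory()].
#' @param level impairment level in 1..3.
#' @param config a [gen_config()].
#' @return The manipulated trajectory with its `disability` metadata set.
#' @export
simulate_disability <- function(traj, level, config = gen_config()) {
  config <- as_gen_config(config)
  if (!level %in% 1:3)
    stop("simulate_disability(): level must be 1, 2 or 3", call. = FALSE)
  level <- as.integer(level)
  if (level == 1L) {
    attr(traj, "disability") <- 1L
    return(traj)
  }
  sf <- config$scale_factor[level]
  amp <- config$tremor_amplitude[level]
  cx <- mean(traj$x); cy <- mean(traj$y)
  x <- cx + (traj$x - cx) * sf
  y <- cy + (traj$y - cy) * sf
  if (amp > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    x <- x + amp * sin(2 * pi * config$tremor_freq * traj$t + ph[1])
    y <- y + amp * sin(2 * pi * config$tremor_freq * traj$t + ph[2])
  }
  md <- mean(traj$d)
  d <- md + config$pupil_shift[level] +
    (traj$d - md) * config$pupil_sd_factor[level]
  out <- raw_trajectory(traj$t, x, y, d, label = attr(traj, "label"),
                        disability = level, writer = attr(traj, "writer"))
  out
}

#' Generate a labeled exemplar database
#'
#' Produces `n_alphabets` exemplars per symbol, mirroring the structure
#' of a multi-alphabet handwriting database. Every (alphabet, symbol)
#' pair derives its own RNG seed from `seed`, so the database is
#' reproducible as a whole and per exemplar. A fraction of exemplars can
#' be drawn from an alternate (mirrored) template form to emulate
#' allographs.
#'
#' @param symbols character vector of symbols (templates come from
#'   [letter_templates()]).
#' @param n_alphabets number of alphabets (writers); >= 2 for
#'   cross-validation use.
#' @param config a [gen_config()].
#' @param seed master seed.
#' @param disability impairment level applied to every exemplar.
#' @return List of labeled [raw_trajectory()] objects with `writer` set
#'   to the alphabet id.
#' @export
generate_database <- function(symbols, n_alphabets, config = gen_config(),
                              seed = 1L, disability = 1L) {
  config <- as_gen_config(config)
  templates <- letter_templates(symbols, box = config$box)
  out <- vector("list", length(symbols) * n_alphabets)
  idx <- 1L
  for (a in seq_len(n_alphabets)) {
    for (si in seq_along(symbols)) {
      sd_i <- (seed + 7919L * (a - 1L) + 104729L * (si - 1L) +
                 1299709L * (disability - 1L)) %% .Machine$integer.max
      tmpl <- templates[[si]]
      if (config$allograph_frac > 0) {
        use_allo <- with_seed(sd_i + 1L, stats::runif(1)) < config$allograph_frac
        if (use_allo) tmpl <- allograph_of(tmpl, config$box)
      }
      out[[idx]] <- generate_trajectory(tmpl, config, seed = sd_i,
                                        disability = disability,
                                        writer = paste0("A", a))
      idx <- idx + 1L
    }
  }
  out
}

#' Preprocess a database of raw trajectories
#'
#' @param db list of [raw_trajectory()] objects.
#' @param config an [ew_config()].
#' @return List of `ew_features`.
#' @export
process_database <- function(db, config = ew_config()) {
  lapply(db, process_trajectory, config = config)
}
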