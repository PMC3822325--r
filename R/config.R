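#' Pipeline and model configuration
#'
#' Collects every tunable parameter of the preprocessing pipeline, the
#' discretization, and the probabilistic model in one validated list.
#' Defaults are the operating values of the eye-writing system: 75 Hz
#' sampling, binomial smoothing of order 20, saccade-trimming threshold of
#' 0.4 px/sample^2 over the first 30 and last 5 samples, a 2.6 Hz spectral
#' split between pursuit and high-frequency components, at most 15
#' via-points at least 2 px apart, Laplace smoothing constant `alpha =
#' 1e-7`, Gaussian histogram smoothing of order 15 / variance 2 for
#' relative-position terms and order 7 / variance 1 for velocity terms, and
#' a velocity discretization scale of 30 (px/s per bin).
#'
#' Domain extents are configurable so that miniature models can be built
#' for testing; their defaults are the full-scale domains: relative
#' displacements in -40..40 (plus a termination marker), velocities in
#' -10..10 (plus marker), sizes `Sx`, `Sy` in 0..50, spectral energy `A` in
#' 0..30, mean pupil diameter in -1..1 (step 0.01), pupil-diameter SD in
#' 0..5 (step 0.1), and three disability levels.
#'
#' @param ... named overrides of the defaults listed below. Unknown keys
#'   are an error.
#'
#' @return A named list of class `ew_config`.
#'
#' @section Keys:
#' \describe{
#'   \item{sample_rate_hz}{nominal sampling rate of gaze records (75).}
#'   \item{binomial_order}{order of the binomial smoothing filter (20).}
#'   \item{accel_threshold}{saccade-trimming acceleration threshold in
#'     px/sample^2 (0.4).}
#'   \item{trim_head, trim_tail}{number of leading/trailing samples
#'     inspected for intrusive saccades (30, 5).}
#'   \item{f0_hz}{frequency split for the spectral-energy feature (2.6).}
#'   \item{min_sep_px}{minimum x *and* y separation below which a via-point
#'     candidate is discarded (2).}
#'   \item{max_via_points}{via-points kept per trajectory (15).}
#'   \item{velocity_scale}{px/s per velocity bin (30).}
#'   \item{position_scale}{px per relative-displacement (and size) bin (2.5).}
#'   \item{a_scale}{(px/s)^2 per spectral-energy bin (150).}
#'   \item{alpha}{Laplace succession-law smoothing constant (1e-7).}
#'   \item{pos_kernel_order, pos_kernel_var}{Gaussian smoothing kernel for
#'     relative-position tables (15, 2).}
#'   \item{vel_kernel_order, vel_kernel_var}{Gaussian smoothing kernel for
#'     velocity tables (7, 1).}
#'   \item{delta_range, vel_range, sx_max, a_max, mup_range, mup_step,
#'     sigmap_max, sigmap_step, n_disability}{domain extents (see above).}
#' }
#' @examples
#' cfg <- ew_config(min_sep_px = 3)
#' cfg$binomial_order
#' @export
ew_config <- function(...) {
  defaults <- list(
    sample_rate_hz  = 75,
    binomial_order  = 20L,
    accel_threshold = 0.4,
    trim_head       = 30L,
    trim_tail       = 5L,
    f0_hz           = 2.6,
    min_sep_px      = 2,
    max_via_points  = 15L,
    velocity_scale  = 30,
    position_scale  = 2.5,
    a_scale         = 150,
    alpha           = 1e-7,
    pos_kernel_order = 15L,
    pos_kernel_var   = 2,
    vel_kernel_order = 7L,
    vel_kernel_var   = 1,
    delta_range  = 40L,
    vel_range    = 10L,
    sx_max       = 50L,
    a_max        = 30L,
    mup_range    = 1,
    mup_step     = 0.01,
    sigmap_max   = 5,
    sigmap_step  = 0.1,
    n_disability = 3L
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("ew_config(): all overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("ew_config(): unknown key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "ew_config")
}

#' @export
print.ew_config <- function(x, ...) {
  cat("<ew_config>\n")
  for (k in names(x)) cat(sprintf("  %-17s %s\n", k, format(x[[k]])))
  invisible(x)
}

as_ew_config <- function(config) {
  if (inherits(config, "ew_config")) return(config)
  if (is.null(config)) return(ew_config())
  do.call(ew_config, as.list(config))
}
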