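#' Discrete variable domains
#'
#' Every variable of the probabilistic model lives on an explicit finite
#' domain. Relative-displacement and velocity domains carry an extra
#' "termination marker" (the probability *well*): a distinguished value,
#' off the numeric scale, that absorbs the probability mass of via-point
#' indices beyond a trajectory's end, so trajectory length needs no
#' variable of its own.
#'
#' @param name domain name.
#' @param values strictly increasing numeric vector (or character for the
#'   symbol domain).
#' @param well logical; append a termination-marker value?
#' @return An object of class `ew_domain`: list with `name`, `values`,
#'   `well`, and `size` (number of values including the marker).
#' @examples
#' d <- domain_spec("delta", -40:40, well = TRUE)
#' d$size   # 82
#' @export
domain_spec <- function(name, values, well = FALSE) {
  if (is.numeric(values) && any(diff(values) <= 0))
    stop("domain_spec(): values must be strictly increasing", call. = FALSE)
  structure(
    list(name = name, values = values, well = isTRUE(well),
         size = length(values) + isTRUE(well)),
    class = "ew_domain")
}

#' @export
print.ew_domain <- function(x, ...) {
  cat(sprintf("<ew_domain> %s: %d values%s\n", x$name, x$size,
              if (x$well) " (incl. termination marker)" else ""))
  invisible(x)
}

# Index of the termination marker inside a well-bearing domain.
well_index <- function(domain) {
  stopifnot(domain$well)
  domain$size
}

#' Instantiate the full domain set of the model
#'
#' @param symbols character vector of known symbols; the unknown-symbol
#'   class `"$"` is appended automatically if absent.
#' @param config an [ew_config()] (controls domain extents).
#' @return Named list of `ew_domain` objects: `delta`, `vel`, `sx`, `sy`,
#'   `a`, `mup`, `sigmap`, `L`, `H`.
#' @examples
#' doms <- ew_domains(c(as.character(1:9), letters))
#' doms$L$size   # 36
#' @export
ew_domains <- function(symbols, config = ew_config()) {
  config <- as_ew_config(config)
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols))
    stop("ew_domains(): duplicated symbols", call. = FALSE)
  if (!"$" %in% symbols) symbols <- c(symbols, "$")
  dr <- config$delta_range; vr <- config$vel_range
  mup_vals <- seq(-config$mup_range, config$mup_range, by = config$mup_step)
  sig_vals <- seq(0, config$sigmap_max, by = config$sigmap_step)
  list(
    delta  = domain_spec("delta", -dr:dr, well = TRUE),
    vel    = domain_spec("vel", -vr:vr, well = TRUE),
    sx     = domain_spec("sx", 0:config$sx_max),
    sy     = domain_spec("sy", 0:config$sx_max),
    a      = domain_spec("a", 0:config$a_max),
    mup    = domain_spec("mup", mup_vals),
    sigmap = domain_spec("sigmap", sig_vals),
    L      = domain_spec("L", symbols),
    H      = domain_spec("H", seq_len(config$n_disability))
  )
}

# Map numeric values onto 1-based domain indices (nearest grid value,
# clamped to the domain ends). Vectorized.
domain_index <- function(domain, x) {
  v <- domain$values
  step <- if (length(v) > 1) v[2] - v[1] else 1
  i <- round((x - v[1]) / step) + 1
  pmin(pmax(i, 1), length(v))
}

#' Count the table entries of the model's terms
#'
#' Reports, for the given domain configuration, the raw number of entries
#' in each conditional probability table of the joint decomposition, and
#' their total. For the full-scale domains a single displacement transition
#' term P(C^i_dx | C^(i-1)_dx, L, H) has 82 * 82 * 36 * 3 = 726,192
#' entries.
#'
#' @param config an [ew_config()].
#' @param n_symbols size of the symbol domain including the unknown class
#'   (36 for the full alphabet).
#' @return list with `terms` (named integer vector; transition terms are
#'   reported per via-point step) and `total`.
#' @examples
#' count_parameters()$terms[["trans_delta_x_per_step"]]  # 726192
#' @export
count_parameters <- function(config = ew_config(), n_symbols = 36L) {
  config <- as_ew_config(config)
  Kd <- 2L * config$delta_range + 1L + 1L   # numeric values + marker
  Kv <- 2L * config$vel_range + 1L + 1L
  Ks <- config$sx_max + 1L
  Ka <- config$a_max + 1L
  Km <- length(seq(-config$mup_range, config$mup_range, by = config$mup_step))
  Kg <- length(seq(0, config$sigmap_max, by = config$sigmap_step))
  nL <- as.integer(n_symbols)
  nH <- config$n_disability
  nstep <- config$max_via_points - 1L
  terms <- c(
    prior_L = nL,
    prior_H = nH,
    first_delta_x = Kd * nL * nH,
    first_delta_y = Kd * nL * nH,
    first_vel_x   = Kv * nL * nH,
    first_vel_y   = Kv * nL * nH,
    trans_delta_x_per_step = Kd * Kd * nL * nH,
    trans_delta_y_per_step = Kd * Kd * nL * nH,
    trans_vel_x_per_step   = Kv * Kv * nL * nH,
    trans_vel_y_per_step   = Kv * Kv * nL * nH,
    size_x = Ks * nL * nH,
    size_y = Ks * nL * nH,
    spectral_energy = Ka * nL * nH,
    pupil_mean = Km * nH,
    pupil_sd   = Kg * nH
  )
  total <- sum(terms[c("prior_L", "prior_H", "first_delta_x", "first_delta_y",
                       "first_vel_x", "first_vel_y", "size_x", "size_y",
                       "spectral_energy", "pupil_mean", "pupil_sd")]) +
    nstep * sum(terms[c("trans_delta_x_per_step", "trans_delta_y_per_step",
                        "trans_vel_x_per_step", "trans_vel_y_per_step")])
  list(terms = terms, total = total)
}
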