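#' Discretize via-points
#'
#' Velocities are divided by `velocity_scale` (px/s per bin), rounded to
#' the nearest integer and clamped to the velocity domain; relative
#' displacements are divided by `position_scale` and clamped to the
#' displacement domain. Rows beyond the trajectory's end (when padding to
#' the model's 15 slots) take the termination-marker value on all four
#' dimensions simultaneously.
#'
#' @param via an `ew_viapoints` data frame (continuous).
#' @param config an [ew_config()].
#' @param pad pad with termination markers up to `config$max_via_points`?
#' @return `data.frame` with integer columns `dx, dy, vx, vy` (binned
#'   values on the numeric scales) and logical `well`.
#' @examples
#' v <- data.frame(k = 1:2, dx = c(0, 50), dy = c(0, -20),
#'                 vx = c(300, 0), vy = c(10, -400), sample = c(1, 10))
#' discretize_via_points(v, pad = FALSE)
#' @export
discretize_via_points <- function(via, config = ew_config(), pad = TRUE) {
  config <- as_ew_config(config)
  clamp <- function(x, r) pmin(pmax(round(x), -r), r)
  out <- data.frame(
    dx = clamp(via$dx / config$position_scale, config$delta_range),
    dy = clamp(via$dy / config$position_scale, config$delta_range),
    vx = clamp(via$vx / config$velocity_scale, config$vel_range),
    vy = clamp(via$vy / config$velocity_scale, config$vel_range),
    well = rep(FALSE, nrow(via)))
  if (pad && nrow(out) < config$max_via_points) {
    extra <- config$max_via_points - nrow(out)
    out <- rbind(out, data.frame(dx = rep(0L, extra), dy = 0L, vx = 0L,
                                 vy = 0L, well = TRUE))
  }
  if (nrow(out) > config$max_via_points)
    out <- out[seq_len(config$max_via_points), ]
  out
}

# Discretized via-points -> 1-based domain indices (matrix n x 4);
# termination marker = last index of its domain.
viapoint_indices <- function(dvp, domains) {
  Kd <- domains$delta$size; Kv <- domains$vel$size
  m <- cbind(
    dx = ifelse(dvp$well, Kd, domain_index(domains$delta, dvp$dx)),
    dy = ifelse(dvp$well, Kd, domain_index(domains$delta, dvp$dy)),
    vx = ifelse(dvp$well, Kv, domain_index(domains$vel, dvp$vx)),
    vy = ifelse(dvp$well, Kv, domain_index(domains$vel, dvp$vy)))
  storage.mode(m) <- "integer"
  m
}

#' Discretize auxiliary features
#'
#' Sizes share the displacement scale (`position_scale` px per bin),
#' spectral energy uses `a_scale` ((px/s)^2 per bin), and the pupil
#' statistics are snapped to their grids. Values beyond a domain end are
#' clamped with a warning.
#'
#' @param aux an `ew_aux`.
#' @param domains an [ew_domains()] set.
#' @param config an [ew_config()].
#' @return Named integer vector of domain indices
#'   (`sx, sy, a, mup, sigmap`).
#' @export
discretize_aux <- function(aux, domains, config = ew_config()) {
  config <- as_ew_config(config)
  vals <- c(sx = aux$sx / config$position_scale,
            sy = aux$sy / config$position_scale,
            a = aux$a / config$a_scale,
            mup = aux$mup, sigmap = aux$sigmap)
  lims <- rbind(sx = range(domains$sx$values),
                sy = range(domains$sy$values),
                a = range(domains$a$values),
                mup = range(domains$mup$values),
                sigmap = range(domains$sigmap$values))
  off <- vals < lims[, 1] - 1e-9 | vals > lims[, 2] + 1e-9
  if (any(off))
    warning("discretize_aux(): value(s) off-domain, clamped: ",
            paste(names(vals)[off], collapse = ", "), call. = FALSE)
  c(sx = domain_index(domains$sx, vals[["sx"]]),
    sy = domain_index(domains$sy, vals[["sy"]]),
    a = domain_index(domains$a, vals[["a"]]),
    mup = domain_index(domains$mup, vals[["mup"]]),
    sigmap = domain_index(domains$sigmap, vals[["sigmap"]]))
}

#' Laplace succession law
#'
#' Additive-smoothing frequency estimate `(n_i + alpha) / (N + alpha K)`:
#' a histogram in which no value ever has zero probability, even when
#' unobserved. With no data it reduces to the uniform distribution `1/K`;
#' as `alpha` grows it shrinks toward uniform; with the operating value
#' `alpha = 1e-7` the empirical frequencies dominate after a single
#' observation.
#'
#' @param n_i observation count(s) for the value(s) of interest.
#' @param N total observation count.
#' @param K domain size.
#' @param alpha smoothing constant (> 0).
#' @return Probabilities, strictly positive.
#' @examples
#' laplace_probability(c(3, 1), 4, 2, alpha = 1)  # 4/6, 2/6
#' @export
laplace_probability <- function(n_i, N, K, alpha = 1e-7) {
  if (any(n_i < 0) || N < 0 || any(n_i > N))
    stop("laplace_probability(): need 0 <= n_i <= N", call. = FALSE)
  if (K < 1) stop("laplace_probability(): K must be >= 1", call. = FALSE)
  if (alpha <= 0) stop("laplace_probability(): alpha must be > 0", call. = FALSE)
  (n_i + alpha) / (N + alpha * K)
}

# Centered truncated discrete Gaussian kernel of support length `order`.
gaussian_kernel <- function(order, variance) {
  order <- as.integer(order)
  if (order < 1) stop("gaussian_kernel(): order must be >= 1", call. = FALSE)
  offs <- seq_len(order) - 1L - (order - 1L) %/% 2L
  w <- exp(-offs^2 / (2 * variance))
  list(offsets = offs, weights = w / sum(w))
}

# Reflect-boundary convolution matrix (rows sum to 1) over k numeric bins.
smoothing_matrix <- function(k, order, variance) {
  kern <- gaussian_kernel(order, variance)
  M <- matrix(0, k, k)
  for (j in seq_along(kern$offsets)) {
    src <- reflect_index(seq_len(k) - kern$offsets[j], k)
    M[cbind(seq_len(k), src)] <- M[cbind(seq_len(k), src)] + kern$weights[j]
  }
  M
}

#' Gaussian smoothing of conditional probability tables
#'
#' Convolves each conditional distribution along its target axis with a
#' truncated discrete Gaussian kernel, making probability peaks "ooze"
#' over neighboring values — a stand-in for the shape variability a larger
#' exemplar database would exhibit. The termination-marker entry (last
#' index, when `has_well`) is excluded: its mass is held fixed and the
#' numeric part is renormalized to the remaining mass. Boundaries use
#' reflection, so a uniform distribution is an exact fixed point.
#'
#' @param tab numeric vector, matrix or array; the target domain is the
#'   first dimension, every remaining slice a conditional distribution.
#' @param kernel_order kernel support length in bins (15 for positions, 7
#'   for velocities).
#' @param kernel_variance kernel variance in bins^2 (2, 1).
#' @param has_well does the target domain end with a termination marker?
#' @return Object of the same shape, every slice still summing to 1.
#' @examples
#' p <- c(rep(0, 7), 1, rep(0, 7))
#' smooth_table(p, 15, 2, has_well = FALSE)
#' @export
smooth_table <- function(tab, kernel_order, kernel_variance,
                         has_well = TRUE) {
  d <- dim(tab)
  k_total <- if (is.null(d)) length(tab) else d[1]
  k_num <- k_total - isTRUE(has_well)
  if (kernel_order > k_num)
    stop("smooth_table(): kernel longer than numeric domain", call. = FALSE)
  M <- smoothing_matrix(k_num, kernel_order, kernel_variance)
  mat <- matrix(as.vector(tab), nrow = k_total)
  num <- M %*% mat[seq_len(k_num), , drop = FALSE]
  if (has_well) {
    wellmass <- mat[k_total, ]
    target <- pmax(1 - wellmass, 0)
  } else {
    target <- rep(1, ncol(mat))
  }
  cs <- colSums(num)
  scale <- ifelse(cs > 0, target / cs, 0)
  num <- sweep(num, 2, scale, `*`)
  out <- if (has_well) rbind(num, mat[k_total, , drop = FALSE]) else num
  if (!is.null(d)) dim(out) <- d
  else out <- as.vector(out)
  out
}

#' Truncated discrete normal fit
#'
#' Fits a normal by the sample mean and standard deviation, evaluates its
#' density on the domain grid, and renormalizes — values outside the
#' domain (e.g. negative sizes or energies) get probability zero by
#' construction. The SD is floored at half a grid step so single-exemplar
#' cells keep a usable (non-degenerate) density.
#'
#' @param samples numeric vector (>= 1 value), in domain units.
#' @param domain an `ew_domain` without termination marker.
#' @return Probability vector over `domain$values`, summing to 1.
#' @examples
#' d <- domain_spec("sx", 0:50)
#' p <- fit_truncated_discrete_normal(c(10, 10, 10), d)
#' which.max(p)  # at value 10
#' @export
fit_truncated_discrete_normal <- function(samples, domain) {
  if (!length(samples))
    stop("fit_truncated_discrete_normal(): empty sample list", call. = FALSE)
  v <- domain$values
  step <- if (length(v) > 1) v[2] - v[1] else 1
  m <- mean(samples)
  s <- if (length(samples) > 1) stats::sd(samples) else 0
  s <- max(s, step / 2)
  dens <- stats::dnorm(v, mean = m, sd = s)
  if (sum(dens) == 0) {  # far off-domain mean: fall back on log-density ranks
    ld <- stats::dnorm(v, mean = m, sd = s, log = TRUE)
    dens <- exp(ld - max(ld))
  }
  dens / sum(dens)
}

new_count_array <- function(dims) {
  a <- array(0L, dim = dims)
  a
}

#' Learn the model from labeled exemplars
#'
#' Supervised parameter identification. For every (symbol, disability)
#' cell, via-point sequences are discretized, padded to 15 slots with the
#' termination marker, and counted into first-via-point tables and 14
#' per-step first-order transition tables for each of the four via-point
#' dimensions. Counts become Laplace succession laws (`alpha = 1e-7`),
#' which are then Gaussian-smoothed along their target axis (order 15 /
#' variance 2 for displacements, 7 / 1 for velocities). Size and
#' spectral-energy terms are truncated discrete normal fits per cell;
#' pupil terms depend on the disability level only. All terms conditioned
#' on the unknown symbol `"$"` are uniform (including the termination
#' marker), and the symbol and disability priors are uniform.
#'
#' Raw counts (and normal-fit sufficient statistics) are stored alongside
#' the probability tables, so adding confirmed trajectories later is exact.
#'
#' @param features list of `ew_features` (see [process_trajectory()]),
#'   each with non-NULL `label` and `disability`.
#' @param config an [ew_config()].
#' @param symbols symbol domain (default: the labels present, sorted).
#' @return Object of class `ew_model`.
#' @export
learn_model <- function(features, config = ew_config(), symbols = NULL) {
  config <- as_ew_config(config)
  labels <- vapply(features, function(f) as.character(f$label), "")
  hs <- vapply(features, function(f) as.integer(f$disability), 1L)
  if (is.null(symbols)) symbols <- sort(unique(labels))
  if ("$" %in% labels)
    stop("learn_model(): exemplars may not be labeled '$'", call. = FALSE)
  domains <- ew_domains(symbols, config)
  nL <- domains$L$size; nH <- domains$H$size
  Kd <- domains$delta$size; Kv <- domains$vel$size
  nvp <- config$max_via_points
  if (!all(hs %in% seq_len(nH)))
    stop("learn_model(): disability labels outside the H domain", call. = FALSE)
  if (!all(labels %in% domains$L$values))
    stop("learn_model(): labels outside the symbol domain", call. = FALSE)

  dimK <- c(dx = Kd, dy = Kd, vx = Kv, vy = Kv)
  counts <- list(
    first = lapply(dimK, function(K) new_count_array(c(K, nL, nH))),
    trans = lapply(dimK, function(K) new_count_array(c(K, K, nvp - 1L, nL, nH))))
  aux_stats <- list(
    sx = array(0, c(3, nL, nH)), sy = array(0, c(3, nL, nH)),
    a = array(0, c(3, nL, nH)),
    mup = matrix(0, 3, nH), sigmap = matrix(0, 3, nH))
  n_exemplars <- matrix(0L, nL, nH,
                        dimnames = list(domains$L$values, domains$H$values))

  lidx <- match(labels, domains$L$values)
  for (e in seq_along(features)) {
    f <- features[[e]]
    li <- lidx[e]; hi <- hs[e]
    dvp <- discretize_via_points(f$via, config, pad = TRUE)
    idx <- viapoint_indices(dvp, domains)
    for (dname in c("dx", "dy", "vx", "vy")) {
      v <- idx[, dname]
      counts$first[[dname]][v[1], li, hi] <-
        counts$first[[dname]][v[1], li, hi] + 1L
      # transition counts laid out [to, from, step, L, H]: target axis first
      steps <- cbind(v[-1], v[-nvp], seq_len(nvp - 1L), li, hi)
      counts$trans[[dname]][steps] <- counts$trans[[dname]][steps] + 1L
    }
    upd <- function(st, val) st + c(1, val, val^2)
    aux_stats$sx[, li, hi] <- upd(aux_stats$sx[, li, hi],
                                  f$aux$sx / config$position_scale)
    aux_stats$sy[, li, hi] <- upd(aux_stats$sy[, li, hi],
                                  f$aux$sy / config$position_scale)
    aux_stats$a[, li, hi] <- upd(aux_stats$a[, li, hi],
                                 f$aux$a / config$a_scale)
    aux_stats$mup[, hi] <- upd(aux_stats$mup[, hi], f$aux$mup)
    aux_stats$sigmap[, hi] <- upd(aux_stats$sigmap[, hi], f$aux$sigmap)
    n_exemplars[li, hi] <- n_exemplars[li, hi] + 1L
  }

  model <- structure(
    list(version = 1L, config = config, domains = domains,
         symbols = domains$L$values, counts = counts, aux_stats = aux_stats,
         n_exemplars = n_exemplars),
    class = "ew_model")
  finalize_model(model)
}

# Turn stored counts/sufficient statistics into the probability tables.
finalize_model <- function(model) {
  config <- model$config
  domains <- model$domains
  nL <- domains$L$size; nH <- domains$H$size
  nvp <- config$max_via_points
  dollar <- match("$", domains$L$values)
  trained <- which(model$n_exemplars > 0, arr.ind = TRUE)
  if (nrow(trained) == 0)
    message("learn_model(): no exemplars; all tables remain at the uniform prior")

  kernel_for <- function(dname) {
    if (dname %in% c("dx", "dy"))
      c(config$pos_kernel_order, config$pos_kernel_var)
    else c(config$vel_kernel_order, config$vel_kernel_var)
  }

  tables <- list(first = list(), trans = list())
  for (dname in c("dx", "dy", "vx", "vy")) {
    K <- dim(model$counts$first[[dname]])[1]
    kern <- kernel_for(dname)
    # uniform everywhere (untrained cells and "$")
    first <- array(1 / K, c(K, nL, nH))
    trans <- array(1 / K, c(K, K, nvp - 1L, nL, nH))
    for (r in seq_len(nrow(trained))) {
      li <- trained[r, 1]; hi <- trained[r, 2]
      if (li == dollar) next
      cf <- model$counts$first[[dname]][, li, hi]
      pf <- laplace_probability(cf, sum(cf), K, config$alpha)
      pf <- smooth_table(pf, kern[1], kern[2], has_well = TRUE)
      first[, li, hi] <- pf
      ct <- model$counts$trans[[dname]][, , , li, hi]  # K x K x (nvp-1)
      Ns <- colSums(ct)                                # K x (nvp-1) totals
      pt <- (ct + config$alpha) /
        rep(Ns + config$alpha * K, each = K)
      pt <- smooth_table(pt, kern[1], kern[2], has_well = TRUE)
      trans[, , , li, hi] <- pt
    }
    tables$first[[dname]] <- first
    tables$trans[[dname]] <- trans
  }

  norm_table <- function(stats_cell, domain) {
    n <- stats_cell[1]
    if (n == 0) return(rep(1 / length(domain$values), length(domain$values)))
    m <- stats_cell[2] / n
    s <- if (n > 1) sqrt(max(stats_cell[3] / n - m^2, 0) * n / (n - 1)) else 0
    v <- domain$values
    step <- if (length(v) > 1) v[2] - v[1] else 1
    s <- max(s, step / 2)
    dens <- stats::dnorm(v, m, s)
    if (sum(dens) == 0) {
      ld <- stats::dnorm(v, m, s, log = TRUE)
      dens <- exp(ld - max(ld))
    }
    dens / sum(dens)
  }

  aux <- list(
    sx = array(0, c(domains$sx$size, nL, nH)),
    sy = array(0, c(domains$sy$size, nL, nH)),
    a = array(0, c(domains$a$size, nL, nH)),
    mup = matrix(0, domains$mup$size, nH),
    sigmap = matrix(0, domains$sigmap$size, nH))
  for (li in seq_len(nL)) for (hi in seq_len(nH)) {
    if (li == dollar) {
      aux$sx[, li, hi] <- 1 / domains$sx$size
      aux$sy[, li, hi] <- 1 / domains$sy$size
      aux$a[, li, hi] <- 1 / domains$a$size
    } else {
      aux$sx[, li, hi] <- norm_table(model$aux_stats$sx[, li, hi], domains$sx)
      aux$sy[, li, hi] <- norm_table(model$aux_stats$sy[, li, hi], domains$sy)
      aux$a[, li, hi] <- norm_table(model$aux_stats$a[, li, hi], domains$a)
    }
  }
  for (hi in seq_len(nH)) {
    aux$mup[, hi] <- norm_table(model$aux_stats$mup[, hi], domains$mup)
    aux$sigmap[, hi] <- norm_table(model$aux_stats$sigmap[, hi], domains$sigmap)
  }

  model$tables <- tables
  model$aux <- aux
  model$prior_L <- rep(1 / nL, nL)
  model$prior_H <- rep(1 / nH, nH)
  model
}

#' @export
print.ew_model <- function(x, ...) {
  cat(sprintf("<ew_model> %d symbols (incl. '$'), %d disability levels, %d exemplars\n",
              x$domains$L$size, x$domains$H$size, sum(x$n_exemplars)))
  invisible(x)
}
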