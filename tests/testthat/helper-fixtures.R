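# Shared fixtures: miniature model configurations small enough for
# exhaustive enumeration, hand-built feature objects, and an independent
# brute-force posterior oracle (explicit enumeration of unobserved
# via-point variables, plain linear arithmetic).

mini_config <- function(...) {
  ew_config(delta_range = 2L, vel_range = 2L, max_via_points = 3L,
            pos_kernel_order = 3L, pos_kernel_var = 1,
            vel_kernel_order = 3L, vel_kernel_var = 1,
            sx_max = 4L, a_max = 4L, mup_range = 0.1, mup_step = 0.1,
            sigmap_max = 0.3, sigmap_step = 0.1, n_disability = 2L,
            position_scale = 1, velocity_scale = 1, a_scale = 1, ...)
}

make_feature <- function(dx, dy, vx, vy, sx = 3, sy = 2, a = 1,
                         mup = 0, sigmap = 0.1,
                         label = "a", disability = 1L, writer = "A1") {
  via <- data.frame(k = seq_along(dx), dx = dx, dy = dy, vx = vx, vy = vy,
                    sample = seq_along(dx))
  class(via) <- c("ew_viapoints", "data.frame")
  structure(list(via = via,
                 aux = structure(list(sx = sx, sy = sy, a = a, mup = mup,
                                      sigmap = sigmap), class = "ew_aux"),
                 label = label, disability = disability, writer = writer),
            class = "ew_features")
}

# A small labeled exemplar set over 3 symbols and 2 disability levels,
# with distinct geometry and lengths per symbol.
mini_exemplars <- function() {
  list(
    make_feature(c(0, 2, -1), c(0, 1, 2), c(1, -1, 0), c(2, 0, -2),
                 sx = 3, sy = 2, a = 1, label = "a", disability = 1L),
    make_feature(c(0, 2, -2), c(0, 1, 2), c(1, -1, 0), c(2, 0, -1),
                 sx = 3, sy = 3, a = 1, label = "a", disability = 2L),
    make_feature(c(0, -2), c(0, -1), c(-2, 1), c(0, 2),
                 sx = 2, sy = 4, a = 2, label = "b", disability = 1L),
    make_feature(c(0, -1), c(0, -2), c(-2, 2), c(1, 2),
                 sx = 2, sy = 4, a = 3, label = "b", disability = 2L),
    make_feature(c(0, 1, 1), c(0, -2, 1), c(0, 2, -1), c(-1, 1, 0),
                 sx = 4, sy = 1, a = 0, label = "c", disability = 1L),
    make_feature(c(0, 1, 2), c(0, -2, 2), c(0, 2, -2), c(-1, 1, 1),
                 sx = 4, sy = 2, a = 0, label = "c", disability = 2L))
}

mini_model <- function(...) {
  learn_model(mini_exemplars(), mini_config(...))
}

# Independent oracle: posterior over symbols (or disability levels) by
# explicit enumeration of the unobserved via-point variables and direct
# products of model tables in linear space.
oracle_posterior <- function(model, ev, k, margin = c("L", "H"),
                             include_aux = FALSE, include_pupil = FALSE) {
  margin <- match.arg(margin)
  nvp <- model$config$max_via_points
  nL <- model$domains$L$size; nH <- model$domains$H$size

  chain_value <- function(dname, li, hi) {
    first <- model$tables$first[[dname]]
    trans <- model$tables$trans[[dname]]
    K <- dim(first)[1]
    v_obs <- ev$vp[, dname]
    n_free <- nvp - k
    if (n_free == 0) {
      val <- first[v_obs[1], li, hi]
      for (i in 2:nvp) val <- val * trans[v_obs[i], v_obs[i - 1], i - 1, li, hi]
      return(val)
    }
    grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n_free)))
    total <- 0
    for (r in seq_len(nrow(grid))) {
      seqv <- c(v_obs[seq_len(k)], grid[r, ])
      val <- first[seqv[1], li, hi]
      for (i in 2:nvp) val <- val * trans[seqv[i], seqv[i - 1], i - 1, li, hi]
      total <- total + val
    }
    total
  }

  joint <- matrix(0, nL, nH)
  for (li in seq_len(nL)) for (hi in seq_len(nH)) {
    val <- 1
    for (dname in c("dx", "dy", "vx", "vy"))
      val <- val * chain_value(dname, li, hi)
    if (include_aux)
      val <- val * model$aux$sx[ev$aux[["sx"]], li, hi] *
        model$aux$sy[ev$aux[["sy"]], li, hi] *
        model$aux$a[ev$aux[["a"]], li, hi]
    if (include_pupil)
      val <- val * model$aux$mup[ev$aux[["mup"]], hi] *
        model$aux$sigmap[ev$aux[["sigmap"]], hi]
    joint[li, hi] <- val
  }
  p <- if (margin == "L") rowSums(joint) else colSums(joint)
  p / sum(p)
}

quiet_nvp <- function(model, f) {
  ev <- discretize_features(model, f)
  attr(novelty_posterior(model, ev), "novel")
}
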