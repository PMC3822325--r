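# Discretization, Laplace succession laws, histogram smoothing, normal
# fits, supervised learning, parameter counting.

test_that("via-point discretization scales, rounds, clamps, and pads", {
  v <- data.frame(k = 1:3, dx = c(0, 50, 99999), dy = c(0, -20, -99999),
                  vx = c(300, 0, 10000), vy = c(10, -400, -10000),
                  sample = 1:3)
  d <- discretize_via_points(v, ew_config(), pad = FALSE)
  expect_equal(d$vx, c(10, 0, 10))      # 300/30 = 10; clamped at +/-10
  expect_equal(d$vy, c(0, -10, -10))    # 10/30 rounds to 0
  expect_equal(d$dx, c(0, 20, 40))      # 50/2.5 = 20; clamped at 40
  expect_equal(d$dy, c(0, -8, -40))
  expect_false(any(d$well))
  padded <- discretize_via_points(v, ew_config(), pad = TRUE)
  expect_equal(nrow(padded), 15)
  expect_true(all(padded$well[4:15]))
})

test_that("Laplace succession law matches its closed form and limits", {
  # empty data: uniform prior
  expect_equal(laplace_probability(rep(0, 5), 0, 5, 1e-7), rep(1 / 5, 5))
  # direct evaluation
  expect_equal(laplace_probability(c(3, 1), 4, 2, alpha = 1), c(4, 2) / 6)
  # small-alpha limit: empirical frequencies, all strictly positive
  p <- laplace_probability(c(5, 0), 5, 2, alpha = 1e-7)
  expect_equal(p[1], 1, tolerance = 1e-6)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(laplace_probability(6, 5, 2), "n_i <= N")
})

test_that("table smoothing oozes peaks, fixes uniform, and preserves well mass", {
  # delta at the center of a wide domain: symmetric unimodal, sums to 1
  p <- c(rep(0, 12), 1, rep(0, 12))
  sm <- smooth_table(p, 15, 2, has_well = FALSE)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(sm, rev(sm), tolerance = 1e-12)
  expect_equal(which.max(sm), 13)
  expect_true(all(diff(sm[6:13]) > 0))
  # direct convolution oracle (kernel support interior to the domain)
  w <- exp(-(-7:7)^2 / 4); w <- w / sum(w)
  expect_equal(sm[6:20], w, tolerance = 1e-12)
  expect_equal(sm[c(1:5, 21:25)], rep(0, 10))
  # uniform is an exact fixed point
  u <- rep(1 / 21, 21)
  expect_equal(smooth_table(u, 7, 1, has_well = FALSE), u, tolerance = 1e-12)
  # well mass is held fixed; numeric part is the smoothed delta scaled
  q <- c(rep(0, 10), 0.5, rep(0, 10), 0.5)  # 21 numeric bins + well
  sq <- smooth_table(q, 7, 1, has_well = TRUE)
  expect_equal(sq[22], 0.5)
  expect_equal(sum(sq[1:21]), 0.5, tolerance = 1e-12)
  expect_equal(sq[1:21] / 0.5, smooth_table(c(rep(0, 10), 1, rep(0, 10)),
                                            7, 1, has_well = FALSE),
               tolerance = 1e-12)
  expect_error(smooth_table(rep(1 / 5, 5), 7, 1, has_well = FALSE), "kernel")
})

test_that("truncated discrete normal fits renormalize over the domain", {
  d <- domain_spec("sx", 0:50)
  p <- fit_truncated_discrete_normal(c(10, 10, 10), d)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(which.max(p), 11)  # value 10
  # large SD: near-uniform, against direct density evaluation
  p2 <- fit_truncated_discrete_normal(c(0, 50, 25, 25), d)
  dens <- dnorm(0:50, mean(c(0, 50, 25, 25)), sd(c(0, 50, 25, 25)))
  expect_equal(p2, dens / sum(dens), tolerance = 1e-12)
  # off-domain mean: monotonically decreasing over the domain
  d2 <- domain_spec("a", 0:30)
  p3 <- fit_truncated_discrete_normal(c(-5, 0, -10, -5), d2)
  expect_true(all(diff(p3) < 0))
  expect_equal(sum(p3), 1, tolerance = 1e-12)
  expect_error(fit_truncated_discrete_normal(numeric(0), d), "empty")
})

test_that("learning accumulates counts into normalized, positive tables", {
  cfg <- mini_config()
  model <- mini_model()
  # every conditional slice sums to 1 and is strictly positive
  for (dname in c("dx", "dy", "vx", "vy")) {
    f <- model$tables$first[[dname]]
    expect_true(all(f > 0))
    expect_equal(apply(f, c(2, 3), sum),
                 matrix(1, dim(f)[2], dim(f)[3]), tolerance = 1e-9)
    tr <- model$tables$trans[[dname]]
    sums <- apply(tr, c(2, 3, 4, 5), sum)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
    expect_true(all(tr > 0))
  }
  # short exemplar: steps beyond its length concentrate on the well
  # (label "b" has 2 via-points; at step 2 its dx transitions -2 -> well)
  li <- match("b", model$domains$L$values)
  Kd <- model$domains$delta$size
  im2 <- match(-2, model$domains$delta$values)
  expect_gt(model$tables$trans$dx[Kd, im2, 2, li, 1], 0.99)
})

test_that("learning is frequency-scale and permutation invariant", {
  cfg <- mini_config()
  ex <- mini_exemplars()
  m1 <- learn_model(ex, cfg)
  m2 <- learn_model(c(ex, ex), cfg)  # duplicated exemplars
  # identical up to the O(alpha) Laplace correction at unobserved entries
  for (dname in c("dx", "vy")) {
    expect_lt(max(abs(m1$tables$first[[dname]] - m2$tables$first[[dname]])),
              1e-6)
    expect_lt(max(abs(m1$tables$trans[[dname]] - m2$tables$trans[[dname]])),
              1e-6)
  }
  m3 <- learn_model(ex[c(4, 1, 6, 3, 2, 5)], cfg)
  expect_identical(m1$tables, m3$tables)
  expect_equal(m1$aux, m3$aux, tolerance = 1e-12)
})

test_that("learned tables match manual counting with identity smoothing", {
  cfg <- mini_config(pos_kernel_order = 1L, vel_kernel_order = 1L)
  ex <- list(
    make_feature(c(0, 1, 2), c(0, 1, 1), c(1, 0, -1), c(1, 1, 0),
                 label = "a", disability = 1L),
    make_feature(c(0, 1, -1), c(0, 1, 1), c(1, 0, -1), c(1, 2, 0),
                 label = "a", disability = 1L))
  m <- learn_model(ex, cfg)
  doms <- m$domains
  li <- match("a", doms$L$values)
  # first via-point dx = 0 for both exemplars -> probability ~ 1 at bin 0
  i0 <- match(0, doms$delta$values)
  expect_equal(m$tables$first$dx[i0, li, 1], 1, tolerance = 1e-6)
  # transition dx: 0 -> 1 observed twice out of two
  i1 <- match(1, doms$delta$values)
  expect_equal(m$tables$trans$dx[i1, i0, 1, li, 1], 1, tolerance = 1e-6)
  # transition dx step 2: 1 -> 2 once, 1 -> -1 once: 1/2 each
  i2 <- match(2, doms$delta$values)
  im1 <- match(-1, doms$delta$values)
  expect_equal(m$tables$trans$dx[i2, i1, 2, li, 1], 0.5, tolerance = 1e-6)
  expect_equal(m$tables$trans$dx[im1, i1, 2, li, 1], 0.5, tolerance = 1e-6)
  # vy step 1: 1 -> 1 once, 1 -> 2 once
  iv1 <- match(1, doms$vel$values)
  iv2 <- match(2, doms$vel$values)
  expect_equal(m$tables$trans$vy[iv1, iv1, 1, li, 1], 0.5, tolerance = 1e-6)
  expect_equal(m$tables$trans$vy[iv2, iv1, 1, li, 1], 0.5, tolerance = 1e-6)
})

test_that("unknown-symbol terms are uniform and priors are uniform", {
  model <- mini_model()
  dollar <- match("$", model$domains$L$values)
  Kd <- model$domains$delta$size
  expect_equal(model$tables$first$dx[, dollar, 1], rep(1 / Kd, Kd))
  expect_equal(model$tables$trans$dy[, , 1, dollar, 2],
               matrix(1 / Kd, Kd, Kd))
  expect_equal(model$aux$sx[, dollar, 1],
               rep(1 / model$domains$sx$size, model$domains$sx$size))
  expect_equal(model$prior_L, rep(1 / model$domains$L$size,
                                  model$domains$L$size))
  expect_equal(model$prior_H, rep(1 / 2, 2))
})

test_that("parameter counts reproduce the published table sizes", {
  pc <- count_parameters()
  expect_identical(unname(pc$terms[["trans_delta_x_per_step"]]), 726192L)
  expect_identical(unname(pc$terms[["pupil_mean"]]), 603L)
  expect_identical(unname(pc$terms[["prior_H"]]), 3L)
  expect_identical(unname(pc$terms[["first_vel_x"]]), 22L * 36L * 3L)
  # total under the documented convention: all first + 14 x transition +
  # aux + priors
  manual <- 36 + 3 + 2 * (82 * 36 * 3) + 2 * (22 * 36 * 3) +
    14 * (2 * 82 * 82 * 36 * 3 + 2 * 22 * 22 * 36 * 3) +
    2 * (51 * 36 * 3) + 31 * 36 * 3 + 201 * 3 + 51 * 3
  expect_identical(as.integer(pc$total), as.integer(manual))
})
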