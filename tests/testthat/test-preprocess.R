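# Deterministic featurization: smoothing, differentiation, saccade
# trimming, via-point extraction, auxiliary features.

test_that("binomial smoothing has unit DC gain and matches direct convolution", {
  expect_equal(binomial_smooth(rep(5, 4), 20), rep(5, 4), tolerance = 1e-12)
  s <- c(3, -1, 4, 1, -5, 9, 2.5)
  expect_identical(binomial_smooth(s, 0), s)
  # interior impulse response = normalized Pascal-triangle coefficients
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- binomial_smooth(imp, 2)
  expect_equal(out[10:12], c(1, 2, 1) / 4, tolerance = 1e-12)
  # order-4 oracle by direct convolution on an interior window
  set.seed(1)
  x <- rnorm(50)
  out4 <- binomial_smooth(x, 4)
  kern <- choose(4, 0:4) / 16
  direct <- sapply(10:40, function(i) sum(kern * x[(i - 2):(i + 2)]))
  expect_equal(out4[10:40], direct, tolerance = 1e-12)
  # constants exactly preserved regardless of length/order
  for (n in c(1, 3, 25)) expect_equal(binomial_smooth(rep(2.5, n), 20),
                                      rep(2.5, n), tolerance = 1e-12)
  expect_error(binomial_smooth(numeric(0), 2), "empty")
})

test_that("finite differences are exact for affine and quadratic signals", {
  dt <- 0.1
  t <- (0:20) * dt
  expect_equal(finite_difference_velocity(3 * t, dt), rep(3, 21),
               tolerance = 1e-12)
  expect_equal(finite_difference_velocity(rep(7, 10), dt), rep(0, 10),
               tolerance = 1e-12)
  v <- finite_difference_velocity(t^2, dt)
  expect_equal(v[2:20], 2 * t[2:20], tolerance = 1e-10)
  expect_error(finite_difference_velocity(1, dt), ">= 2 samples")
  expect_error(finite_difference_velocity(c(1, 2), 0), "dt")
})

fake_kinematic <- function(n, accel, vx = rep(1, n), vy = rep(1, n)) {
  structure(list(t = (seq_len(n) - 1) / 75, x = cumsum(vx) / 75,
                 y = cumsum(vy) / 75, vx = vx, vy = vy, accel = accel,
                 dt = 1 / 75, pupil = rep(0, n), label = NULL,
                 disability = NULL, writer = NULL),
            class = "ew_kinematic")
}

test_that("saccade trimming removes only above-threshold end windows", {
  n <- 60
  quiet <- fake_kinematic(n, rep(0.1, n))
  expect_identical(trim_intrusive_saccades(quiet), quiet)
  # spike at sample 10 inside the head window: samples 1..10 removed
  acc <- rep(0.1, n); acc[10] <- 1.0
  trimmed <- trim_intrusive_saccades(fake_kinematic(n, acc))
  expect_equal(length(trimmed$t), n - 10)
  expect_equal(trimmed$t[1], 10 / 75)
  # same spike at sample 40, outside both windows: untouched
  acc2 <- rep(0.1, n); acc2[40] <- 1.0
  expect_identical(trim_intrusive_saccades(fake_kinematic(n, acc2)),
                   fake_kinematic(n, acc2))
  # tail: spike in last 5 samples removes from the spike onward
  acc3 <- rep(0.1, n); acc3[n - 2] <- 1.0
  t3 <- trim_intrusive_saccades(fake_kinematic(n, acc3))
  expect_equal(length(t3$t), n - 3)
  # idempotence on these fixtures
  t1 <- trim_intrusive_saccades(fake_kinematic(n, acc))
  expect_identical(trim_intrusive_saccades(t1), t1)
  # refusal to trim to fewer than 2 points
  short <- fake_kinematic(3, c(0.1, 0.1, 1.0))
  expect_warning(out <- trim_intrusive_saccades(short, head = 3, tail = 3),
                 class = "eyewrite_degenerate_trajectory")
  expect_identical(out, short)
})

test_that("via-point extraction finds velocity zero crossings at extrema", {
  # straight constant-velocity segment: exactly start and end
  n <- 100
  straight <- fake_kinematic(n, rep(0, n), vx = rep(75, n), vy = rep(37.5, n))
  vp <- extract_via_points(straight)
  expect_equal(nrow(vp), 2)
  expect_equal(vp$dx[1], 0)
  expect_equal(vp$dx[2], straight$x[n] - straight$x[1], tolerance = 1e-12)
  # x(t) = t, y = sin(2 pi t): interior via-points at the two y extrema
  nn <- 201
  tt <- seq(0, 1, length.out = nn)
  sine <- structure(list(t = tt, x = 100 * tt, y = 30 * sin(2 * pi * tt),
                         vx = rep(100, nn), vy = 60 * pi * cos(2 * pi * tt),
                         accel = rep(0, nn), dt = tt[2], pupil = rep(0, nn),
                         label = NULL, disability = NULL, writer = NULL),
                    class = "ew_kinematic")
  vp2 <- extract_via_points(sine)
  expect_equal(nrow(vp2), 4)
  interior <- vp2$sample[2:3]
  expect_equal(tt[interior], c(0.25, 0.75), tolerance = 0.01)
  # circle traversed once from a non-extremal phase: 4 interior extrema
  th0 <- pi / 6
  ang <- th0 + 2 * pi * tt
  circ <- structure(list(t = tt, x = 20 * cos(ang), y = 20 * sin(ang),
                         vx = -40 * pi * sin(ang), vy = 40 * pi * cos(ang),
                         accel = rep(0, nn), dt = tt[2], pupil = rep(0, nn),
                         label = NULL, disability = NULL, writer = NULL),
                    class = "ew_kinematic")
  vp3 <- extract_via_points(circ)
  expect_equal(nrow(vp3), 6)
  # telescoping: displacements sum to net displacement
  expect_equal(sum(vp3$dx), circ$x[nn] - circ$x[1], tolerance = 1e-9)
  expect_equal(sum(vp3$dy), circ$y[nn] - circ$y[1], tolerance = 1e-9)
  # temporal ordering and endpoints
  expect_true(all(diff(vp3$sample) > 0))
  expect_equal(vp3$sample[c(1, 6)], c(1, nn))
  expect_error(extract_via_points(fake_kinematic(1, 0)), ">= 2 samples")
})

test_that("min_sep rejects candidates close in both x and y, max_count truncates", {
  nn <- 301
  tt <- seq(0, 3, length.out = nn)
  # small-amplitude wiggle: extrema are < 2 px apart in both axes
  wig <- structure(list(t = tt, x = 0.5 * sin(4 * pi * tt), y = 0.3 * cos(4 * pi * tt),
                        vx = 2 * pi * cos(4 * pi * tt),
                        vy = -1.2 * pi * sin(4 * pi * tt),
                        accel = rep(0, nn), dt = tt[2], pupil = rep(0, nn),
                        label = NULL, disability = NULL, writer = NULL),
                   class = "ew_kinematic")
  expect_equal(nrow(extract_via_points(wig, min_sep = 2)), 2)
  # with min_sep 0 the same wiggle yields many, capped at max_count
  many <- extract_via_points(wig, max_count = 5, min_sep = 0)
  expect_equal(nrow(many), 5)
})

test_that("auxiliary features: sizes, pupil stats, and Parseval-checked band energy", {
  n <- 150  # 2 s at 75 Hz: integer periods for 1 Hz and 5 Hz
  tt <- (seq_len(n) - 1) / 75
  base <- fake_kinematic(n, rep(0, n))
  base$pupil <- rep(0.2, n)
  aux <- compute_aux_features(base, f0 = 2.6, sample_rate = 75)
  expect_equal(aux$mup, 0.2)
  expect_equal(aux$sigmap, 0)
  expect_equal(aux$sx, max(base$x) - min(base$x))
  # pure 1 Hz velocity: all power below the 2.6 Hz split
  low <- base; low$vx <- 50 * sin(2 * pi * 1 * tt); low$vy <- rep(0, n)
  expect_lt(compute_aux_features(low, f0 = 2.6, sample_rate = 75)$a, 1e-18)
  # 1 Hz + 5 Hz: band energy equals the 5 Hz component's mean square power
  mix <- base
  hi <- 12 * sin(2 * pi * 5 * tt)
  mix$vx <- 50 * sin(2 * pi * 1 * tt) + hi
  mix$vy <- rep(0, n)
  a <- compute_aux_features(mix, f0 = 2.6, sample_rate = 75)$a
  expect_equal(a, mean(hi^2), tolerance = 1e-9)  # Parseval on the isolated tone
  expect_equal(a, 12^2 / 2, tolerance = 1e-9)
  expect_error(compute_aux_features(base, f0 = 2.6, sample_rate = 5),
               "sample_rate")
})

test_that("full preprocessing is translation invariant", {
  tmpl <- letter_templates()[[2]]
  tr <- generate_trajectory(tmpl, gen_config(), seed = 99)
  tr2 <- tr; tr2$x <- tr2$x + 312.5; tr2$y <- tr2$y - 87.1
  f1 <- process_trajectory(tr)
  f2 <- process_trajectory(tr2)
  expect_equal(f1$via$dx, f2$via$dx, tolerance = 1e-9)
  expect_equal(f1$via$dy, f2$via$dy, tolerance = 1e-9)
  expect_equal(f1$via$vx, f2$via$vx, tolerance = 1e-9)
  expect_equal(unclass(f1$aux), unclass(f2$aux), tolerance = 1e-9)
})

test_that("raw trajectory constructor validates its invariants", {
  expect_error(raw_trajectory(0, 1, 1), "2 samples")
  expect_error(raw_trajectory(c(0, 1, 1.5), 1:3, 1:3), "uniform")
  expect_error(raw_trajectory(c(0, 1, 0.5), 1:3, 1:3), "increasing")
  expect_error(raw_trajectory(c(0, 1), c(1, NA), c(1, 2)), "finite")
})
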