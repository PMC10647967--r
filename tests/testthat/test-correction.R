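test_that("phase inversion is detected from the correlation sign", {
  t <- seq(0, 30, by = 0.2)
  w <- sin(2 * pi * t / 4)
  expect_equal(detect_phase_inversion(w, -w), -1)
  expect_equal(detect_phase_inversion(w, w), +1)
  expect_error(detect_phase_inversion(rep(1, 10), rep(0, 10)),
               "zero-variance")
})

test_that("global matching maps percentile endpoints onto the target range", {
  # (P100, P0) with a [0,1] shroud and [0,10] target: pure scaling by 10
  w_as <- seq(0, 1, length.out = 50)
  w_4d <- c(0, 10, runif(48, 0, 10))
  out <- global_match(w_as, w_4d, matching_params(100, 0, 11))
  expect_equal(out, 10 * w_as)

  # identity when shroud and target coincide
  w <- sin(seq(0, 6 * pi, length.out = 100))
  expect_equal(global_match(w, w, matching_params(100, 0, 11)), w)

  # direct evaluation with P85 = 8, P10 = 2 of the averaged signal
  as_avg <- 2 + 0.4 * ((1:21) - 3)      # quantile(.,0.85)=8, quantile(.,0.10)=2
  expect_equal(as4dpm:::.percentile(as_avg, 85), 8)
  expect_equal(as4dpm:::.percentile(as_avg, 10), 2)
  w_4d2 <- c(0, 10)
  out2 <- global_match(c(5, 2, 8), w_4d2, matching_params(85, 10, 11),
                       as_avg = as_avg)
  expect_equal(out2, c(5, 0, 10))

  expect_error(global_match(rep(1, 10), c(0, 1), matching_params(85, 10, 11),
                            as_avg = rep(1, 10)), "degenerate")
})

test_that("global matching is affine and order-preserving", {
  set.seed(8)
  w_as <- rnorm(200)
  w_4d <- 3 * sin(seq(0, 8 * pi, length.out = 200)) + 1
  out <- global_match(w_as, w_4d, matching_params(85, 10, 11))
  expect_equal(order(out), order(w_as))
  # endpoint mapping: P_lower -> P0(4D), P_upper -> P100(4D)
  pl <- as4dpm:::.percentile(w_as, 10); pu <- as4dpm:::.percentile(w_as, 85)
  mapped <- global_match(c(pl, pu), w_4d, matching_params(85, 10, 11),
                         as_avg = w_as)
  expect_equal(mapped, c(min(w_4d), max(w_4d)))
})

test_that("local matching is exact for identical and affine discrepancies", {
  t <- seq(0, 60, by = 0.2)
  q <- sin(2 * pi * t / 4) + 0.1 * t / 10
  expect_equal(local_match(q, q, 21L), q)
  expect_equal(local_match(q, 2 * q + 3, 21L), 2 * q + 3, tolerance = 1e-12)
  # single full-length window: output range equals the reference range
  p <- 5 * q - 2
  n <- length(q); w <- if (n %% 2 == 0) n - 1 else n
  out <- local_match(q[1:w], p[1:w], w)
  expect_equal(range(out), range(p[1:w]))
  # flat target window: pure shift to the reference mean
  flat <- rep(1, 31)
  ref <- sin(seq(0, 2 * pi, length.out = 31))
  expect_equal(local_match(flat, ref, 31L), rep(mean(ref), 31))
  expect_error(local_match(q, q, 20L), "odd")
})

test_that("local matching output stays within the local reference envelope", {
  set.seed(12)
  t <- seq(0, 60, by = 0.2)
  q <- sin(2 * pi * t / 3.8)
  p <- 1.3 * sin(2 * pi * t / 3.8 + 0.1) + 0.2 * rnorm(length(t))
  out <- local_match(q, p, 21L)
  for (i in seq_along(out)) {
    lo <- max(1, i - 20); hi <- min(length(p), i + 20)
    expect_gte(out[i], min(p[lo:hi]) - 1e-9)
    expect_lte(out[i], max(p[lo:hi]) + 1e-9)
  }
})

test_that("shroud correction repairs an amplitude-underestimated target", {
  t <- seq(0, 60, by = 0.2)
  phi <- t / 3.9
  truth <- cbind(LR = -0.15, SI = -1, AP = -0.3)[rep(1, length(t)), ] *
    matrix(11 * cos(pi * phi)^4, length(t), 3)
  w_as <- 1.4 * truth[, "SI"] + 3          # faithful diaphragm surrogate
  w_4d <- 0.7 * truth                      # underestimated motion range
  corr <- correct_waveform(w_4d, w_as, matching_params(100, 0, 21))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  for (d in 1:3) {
    expect_lt(rmse(corr$samples[, d], truth[, d]),
              rmse(w_4d[, d], truth[, d]) + 1e-9)
  }
  expect_equal(unname(corr$signs), c(1, 1, 1))

  # negative LR correlation is sign-corrected
  truth2 <- truth; truth2[, "LR"] <- -truth2[, "LR"]
  corr2 <- correct_waveform(0.7 * truth2, w_as, matching_params(100, 0, 21))
  expect_equal(unname(corr2$signs), c(-1, 1, 1))
})

test_that("correction is nearly neutral when the target is already right", {
  t <- seq(0, 60, by = 0.2)
  phi <- t / 3.9
  truth <- matrix(-11 * cos(pi * phi)^4, length(t), 1)
  w_as <- 1.4 * truth[, 1] + 3
  corr <- correct_waveform(truth, w_as, matching_params(100, 0, 21))
  amp <- diff(range(truth))
  expect_lt(sqrt(mean((corr$samples[, 1] - truth[, 1])^2)), 0.05 * amp)
  expect_equal(nrow(corr$samples), length(t))
})
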