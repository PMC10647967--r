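test_that("error metrics match hand-computed values", {
  pred <- matrix(0, 5, 3)
  actual <- matrix(0, 5, 3)
  expect_equal(error_metrics(pred, actual)$rmse_3d, 0)
  expect_equal(error_metrics(pred, actual)$pct_within, 100)

  # constant 3 mm SI offset: 3D error is exactly the threshold, strict
  # inequality counts it as outside
  off <- actual; off[, 2] <- off[, 2] + 3
  m <- error_metrics(off, actual)
  expect_equal(m$pct_within, 0)
  expect_equal(unname(m$rmse[2]), 3)
  expect_equal(error_metrics(off, actual, strict = FALSE)$pct_within, 100)

  # SI errors 1..5 mm: 3D RMSE = sqrt(55/5), 2 of 5 frames below 3 mm
  tab <- matrix(0, 5, 3); tab[, 2] <- 1:5
  m2 <- error_metrics(tab, matrix(0, 5, 3))
  expect_equal(m2$rmse_3d, sqrt(55 / 5))
  expect_equal(m2$pct_within, 40)
  expect_error(error_metrics(tab[0, , drop = FALSE],
                             tab[0, , drop = FALSE]), "empty")
})

test_that("metrics agree with a brute-force recomputation on random inputs", {
  set.seed(19)
  pred <- matrix(rnorm(300), 100, 3)
  actual <- matrix(rnorm(300), 100, 3)
  m <- error_metrics(pred, actual, threshold = 2)
  norms <- sapply(seq_len(100), function(i)
    sqrt(sum((pred[i, ] - actual[i, ])^2)))
  expect_equal(m$rmse_3d, sqrt(mean(norms^2)))
  expect_equal(m$pct_within, 100 * sum(norms < 2) / 100)
  expect_equal(unname(m$rmse[1]), sqrt(mean((pred[, 1] - actual[, 1])^2)))
})

test_that("baseline drift reproduces constructed shifts", {
  t <- seq(0, 60, by = 0.2)
  w <- -3 * cos(pi * t / 3.8)^4
  expect_equal(baseline_drift(w, w)$drift, 0)
  d <- baseline_drift(w, w + 1.5)
  expect_equal(d$drift, 1.5)
  expect_equal(d$bl_test - d$bl_train, 1.5)
})

test_that("simulated surrogate drift appears in the drift statistic", {
  drifts <- sapply(1:10, function(seed) {
    p <- breathing_params(seed = seed, drift_rate = 0.5, noise_sd = 0.05)
    case <- simulate_case(p, build_schedule(), render = FALSE)
    ir <- rowMeans(case$ir_traces)
    baseline_drift(ir[1:302], ir[303:351])$drift
  })
  # window midpoints 30 s and ~66.5 s: expected ~0.5 * 36.5/60 = 0.30 mm
  expect_lt(abs(mean(drifts) - 0.30), 0.12)
})

test_that("clean clinical-scenario predictions are sub-0.1 mm and ordering holds", {
  case <- small_case(51, width = 32L, noise_sd = 0)
  a <- run_scenario(case, "CL")
  expect_lt(a$metrics$rmse_3d, 0.1)
  b <- run_scenario(case, "4D-CBCT", amplitude_shrink = 0.7)
  expect_gt(b$metrics$rmse_3d, a$metrics$rmse_3d)
  expect_equal(nrow(a$predicted), 351 - 302)
})

test_that("dual and single shroud scenarios coincide for identical imagers", {
  case <- small_case(52, width = 32L)   # noiseless: both stacks identical
  pars <- matching_params(85, 10, 21)
  rc <- run_scenario(case, "AS-4D-CBCT-dual", pars, amplitude_shrink = 0.7)
  rd <- run_scenario(case, "AS-4D-CBCT-single1", pars, amplitude_shrink = 0.7)
  expect_equal(rc$metrics$rmse_3d, rd$metrics$rmse_3d, tolerance = 1e-6)
})

test_that("long-term evaluation on a drifted second session degrades accuracy", {
  case <- small_case(53, width = 32L)
  p2 <- breathing_params(seed = 530, drift_rate = 2, noise_sd = 0.1)
  case2 <- simulate_case(p2, build_schedule(), image_shape = c(256L, 32L))
  r <- run_scenario(case, "CL", eval_case = case2)
  expect_false(is.null(r$long_term))
  expect_gt(r$long_term$rmse_3d, r$metrics$rmse_3d)
})

test_that("a 1x1 parameter grid equals the direct scenario run and is deterministic", {
  case <- small_case(54, width = 32L)
  g <- parameter_grid_report(case, percentile_candidates = list(c(85, 10)),
                             window_candidates = 21L,
                             amplitude_shrink = 0.7)
  direct <- run_scenario(case, "AS-4D-CBCT-dual", matching_params(85, 10, 21),
                         amplitude_shrink = 0.7)
  expect_equal(g$grid$pct_within, direct$metrics$pct_within)
  g2 <- parameter_grid_report(case, percentile_candidates = list(c(85, 10)),
                              window_candidates = 21L,
                              amplitude_shrink = 0.7)
  expect_identical(g$grid, g2$grid)
})

test_that("case export is byte-identical across repeated writes", {
  case <- simulate_case(breathing_params(seed = 61, proj_noise_sd = 0.02,
                                         amplitude = c(1, 4, 2),
                                         diaphragm_scale = 1.2),
                        build_schedule(1.5, 6, 0.3),
                        image_shape = c(64L, 16L), edge_width = 10)
  d1 <- file.path(tempdir(), "case_a"); d2 <- file.path(tempdir(), "case_b")
  write_case(case, d1); write_case(case, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  st <- read_projection_stack(file.path(d1, "imager1.tif"),
                              file.path(d1, "imager1_frames.csv"))
  expect_equal(dim(st$frames), dim(case$projections[[1]]$frames))
  expect_equal(st$frames, case$projections[[1]]$frames, tolerance = 1e-6)
})
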