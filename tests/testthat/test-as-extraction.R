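test_that("constant frames collapse to an all-zero shroud column", {
  st <- make_stack(array(0.5, c(32L, 8L, 5L)))
  img <- make_as_image(st)
  expect_equal(dim(img$matrix), c(32L, 5L))
  expect_true(all(img$matrix == 0))
  st0 <- make_stack(array(0, c(8L, 4L, 3L)))
  expect_error(make_as_image(st0), "non-positive")
})

test_that("shroud ridge follows the rendered edge", {
  rows <- 120 + 40 * sin(2 * pi * (0:99) / 25)
  st <- edge_stack(rows, c(256L, 16L), edge_width = 20, texture_amp = 0)
  img <- make_as_image(st)
  ridge <- apply(abs(img$matrix), 2, which.max)
  expect_gt(cor(ridge, rows), 0.99)
})

test_that("superimposition recovers integer row shifts", {
  rows <- 120 + 30 * sin(2 * pi * (0:79) / 20)
  st <- edge_stack(rows, c(256L, 16L), edge_width = 20)
  a1 <- make_as_image(st)
  # shifted copy: content moved down by 7 rows
  a2 <- a1
  a2$matrix <- rbind(matrix(a1$matrix[1, ], 7, ncol(a1$matrix),
                            byrow = TRUE),
                     a1$matrix[1:(nrow(a1$matrix) - 7), ])
  sup <- superimpose_as(a1, a2)
  expect_equal(attr(sup, "shift"), -7L)
  rows_overlap <- seq_len(nrow(sup$matrix)) + sup$row_offset
  expect_equal(sup$matrix, a1$matrix[rows_overlap, ], tolerance = 1e-12)
  # identity case
  supi <- superimpose_as(a1, a1)
  expect_equal(attr(supi, "shift"), 0L)
  expect_equal(supi$matrix, a1$matrix)
})

test_that("superimposition recovers shifts under noise (SNR ~5)", {
  set.seed(77)
  rows <- 120 + 30 * sin(2 * pi * (0:79) / 20)
  st <- edge_stack(rows, c(256L, 16L), edge_width = 20)
  a1 <- make_as_image(st)
  sdn <- sd(a1$matrix) / 5
  for (k in c(-20L, -3L, 0L, 12L, 20L)) {
    m2 <- a1$matrix[pmin(pmax(seq_len(nrow(a1$matrix)) - k, 1),
                         nrow(a1$matrix)), ]
    a2 <- a1
    a2$matrix <- m2 + matrix(rnorm(length(m2), 0, sdn), nrow(m2))
    # content moved down by k rows is undone by a -k registration shift
    expect_equal(attr(superimpose_as(a1, a2), "shift"), -k)
  }
})

test_that("trimming keeps the requested band and finds the active band", {
  rows <- 120 + 30 * sin(2 * pi * (0:79) / 20)
  st <- edge_stack(rows, c(256L, 16L), edge_width = 20)
  img <- make_as_image(st)
  full <- trim_as(img, c(1L, nrow(img$matrix)))
  expect_equal(full$matrix, img$matrix)
  one <- trim_as(img, "auto", margin = 0L)
  expect_equal(nrow(one$matrix), 1L)
  auto <- trim_as(img, "auto", margin = 25L)
  center <- auto$row_offset + (nrow(auto$matrix) + 1) / 2
  expect_gt(center, min(rows) - 25)
  expect_lt(center, max(rows) + 25 + 20)
  expect_error(trim_as(img, c(40L, 10L)), "band")
})

test_that("local normalization maps constants to constants and equalizes tiles", {
  img <- structure(list(matrix = matrix(3.5, 64L, 64L), row_pitch = 0.2,
                        frame_times = 1:64, provenance = "single:1",
                        row_offset = 0L), class = "as_image")
  out <- local_normalize(img, window = 5L)
  expect_true(all(out$matrix == 0.5))
  expect_error(local_normalize(img, window = 4L), "odd")
  expect_error(local_normalize(img, window = 101L), "larger than image")
})

test_that("local normalization is insensitive to a global illumination ramp", {
  case <- small_case(31, width = 16L)
  img <- trim_as(make_as_image(case$projections[[1]]), "auto", margin = 60L)
  base <- local_normalize(img, window = 61L)$matrix
  ramped <- img
  ramped$matrix <- img$matrix +
    outer(seq(0, 0.01, length.out = nrow(img$matrix)),
          rep(1, ncol(img$matrix)))
  out <- local_normalize(ramped, window = 61L)$matrix
  expect_lt(sqrt(mean((out - base)^2)) / sd(base), 0.05)
})

test_that("tile means are near-equal after normalization", {
  case <- small_case(32, width = 16L)
  img <- trim_as(make_as_image(case$projections[[1]]), "auto", margin = 60L)
  out <- local_normalize(img, window = 61L)$matrix
  h <- nrow(out); w <- ncol(out)
  rb <- ceiling(seq_len(h) / (h / 8)); cb <- ceiling(seq_len(w) / (w / 8))
  means <- as.vector(tapply(out, list(rb[row(out)], cb[col(out)]), mean))
  expect_lt(sd(means) / mean(means), 0.1)
})

test_that("PCA waveform tracks the true diaphragm trace", {
  case <- small_case(33, width = 32L)
  ti <- 1:302
  w <- extract_as_signal(case$projections, frames = ti)
  # sign convention: +1 = inferior displacement = -SI
  expect_gt(cor(w$samples, -case$diaphragm_si[ti]), 0.99)
  expect_equal(length(w$samples), length(ti))
})

test_that("zero-variance shroud images are rejected", {
  img <- structure(list(matrix = matrix(1, 10L, 4L), row_pitch = 0.2,
                        frame_times = 1:4, provenance = "single:1",
                        row_offset = 0L), class = "as_image")
  expect_error(extract_as_waveform(img), "zero-variance")
})

test_that("waveform is invariant to global intensity scaling of the stack", {
  case <- small_case(34, width = 16L)
  ti <- 1:302
  st <- case$projections[[1]]
  w1 <- extract_as_signal(st, frames = ti)
  st2 <- st
  st2$frames <- st$frames * 2
  w2 <- extract_as_signal(st2, frames = ti)
  # log(2x) = log 2 + log x: the shroud gradient is unchanged
  expect_equal(w1$samples, w2$samples, tolerance = 1e-8)
})

test_that("dual-imager waveform is no worse than the worse single imager", {
  for (seed in c(41, 42)) {
    case <- small_case(seed, proj_noise_sd = 0.05, width = 32L)
    ti <- 1:302
    truth <- -case$diaphragm_si[ti]
    rd <- cor(extract_as_signal(case$projections, frames = ti)$samples, truth)
    r1 <- cor(extract_as_signal(case$projections[1], frames = ti)$samples, truth)
    r2 <- cor(extract_as_signal(case$projections[2], frames = ti)$samples, truth)
    expect_gte(rd, min(r1, r2) - 1e-9)
  }
})
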