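test_that("NCC recovers trivial and integer lags exactly", {
  x <- bandlimited_rf(4096, seed = 1)
  ref <- x[1001:1100]
  m <- 10L
  same <- ncc_1d(ref, x[(1001 - m):(1100 + m)])
  expect_equal(same$lag, 0)
  expect_equal(same$peak, 1.0, tolerance = 1e-12)
  # segment vs itself delayed by exactly 3 samples
  shifted <- ncc_1d(ref, x[(1001 - m + 3):(1100 + m + 3)])
  expect_equal(shifted$lag, -3)
  expect_equal(shifted$peak, 1.0, tolerance = 1e-12)
  # constructed: the pattern 3 samples deeper in the search segment
  deeper <- ncc_1d(x[1004:1103], x[(1001 - m):(1100 + m)])
  expect_equal(deeper$lag, 3)
})

test_that("zero-variance segments and boundary peaks are flagged", {
  z <- ncc_1d(rep(1, 50), rnorm(60))
  expect_identical(z$flag, 1L)
  expect_identical(z$peak, 0)
  x <- bandlimited_rf(4096, seed = 2)
  # true shift equal to the search bound lands the peak on the boundary
  b <- ncc_1d(x[1006:1105], x[(1001 - 5):(1100 + 5)])
  expect_identical(b$flag, 2L)
})

test_that("subsample estimates match a sinc-upsampled NCC oracle", {
  x <- bandlimited_rf(4096, seed = 3)
  start <- 1501L; L <- 120L; m <- 8L
  delta <- 2.30
  y <- subsample_shift(x, delta)
  ref <- x[start:(start + L - 1)]
  est <- ncc_1d(ref, y[(start - m):(start + L - 1 + m)])
  expect_lt(abs(est$lag - delta), 0.05)
  # oracle: NCC on a 100x-upsampled lag grid
  oracle <- ncc_oracle_lag(ref, y, start, L, max_lag = 4, res = 0.01)
  expect_lt(abs(est$lag - oracle), 0.05)
  expect_lt(abs(oracle - delta), 0.02)
})

test_that("subsample bias stays below 0.05 samples over the unit-cell sweep", {
  x <- bandlimited_rf(8192, seed = 4)
  start <- 2001L; L <- 120L; m <- 8L
  ref <- x[start:(start + L - 1)]
  errs <- vapply(seq(0, 0.9, by = 0.1), function(delta) {
    y <- subsample_shift(x, delta)
    est <- ncc_1d(ref, y[(start - m):(start + L - 1 + m)])
    abs(est$lag - delta)
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("R and C++ tracking paths agree and the sign convention holds", {
  su <- micro_setup(n_elem = 4L, step = 0.1e-3, depth = c(20e-3, 30e-3),
                    lines_per_degree = 0.25)
  set.seed(5)
  cl <- point_cloud(cbind(runif(60, -2e-3, 2e-3), runif(60, -2e-3, 2e-3),
                          runif(60, 21e-3, 29e-3)), rnorm(60))
  chd <- simulate_sequence(cl, su$scheme, su$probe, su$medium, su$pulse,
                           su$fs, 1, grid = su$grid)
  v0 <- das_beamform(chd, 1, su$grid)
  # shift the whole volume content one sample shallower = motion toward the
  # transducer by one axial step -> positive displacement
  v1 <- v0
  n <- dim(v0$bf)[1]
  v1$bf[1:(n - 1), , ] <- v0$bf[2:n, , ]
  cfg <- tracking_config(window_length = 2e-3, overlap = 0.5, max_lag = 0.5e-3)
  dp <- track_pair(v0, v1, cfg)
  expect_equal(median(dp$d[dp$valid]), su$grid$axial_step, tolerance = 1e-6)
  # identical volumes: zero displacement, quality 1
  dp0 <- track_pair(v0, v0, cfg)
  expect_equal(max(abs(dp0$d[dp0$valid])), 0, tolerance = 1e-9)
  expect_true(all(dp0$quality[dp0$valid] > 0.999))
  # R reference path (ncc_1d) agrees with the C++ kernel window by window
  ts <- ewi3d:::tracking_samples(su$grid, cfg)
  a <- 3L; e <- 2L
  line0 <- v0$bf[, a, e]; line1 <- v1$bf[, a, e]
  for (w in seq(2, length(ts$starts) - 1, by = 3)) {
    s0 <- ts$starts[w]
    if (s0 - ts$max_lag < 1 || s0 + ts$wlen - 1 + ts$max_lag > n) next
    r <- ncc_1d(line0[s0:(s0 + ts$wlen - 1)],
                line1[(s0 - ts$max_lag):(s0 + ts$wlen - 1 + ts$max_lag)])
    expect_equal(-r$lag * su$grid$axial_step, dp$d[w, a, e], tolerance = 1e-10)
  }
})

test_that("tracking is antisymmetric on high-quality windows", {
  su <- micro_setup(n_elem = 4L, step = 0.1e-3, depth = c(20e-3, 30e-3),
                    lines_per_degree = 0.25)
  set.seed(6)
  cl <- point_cloud(cbind(runif(80, -2e-3, 2e-3), runif(80, -2e-3, 2e-3),
                          runif(80, 21e-3, 29e-3)), rnorm(80))
  cl2 <- cl; cl2$positions[, 3] <- cl2$positions[, 3] - 40e-6
  mk <- function(c_) {
    chd <- simulate_sequence(c_, su$scheme, su$probe, su$medium, su$pulse,
                             su$fs, 1, grid = su$grid)
    das_beamform(chd, 1, su$grid)
  }
  v0 <- mk(cl); v1 <- mk(cl2)
  # note: an RF correlation sampled at ~3.7 samples per carrier period dips
  # to ~0.65 at half-sample true shifts, so 0.5 is the realistic floor
  cfg <- tracking_config(window_length = 3e-3, overlap = 0.8, max_lag = 0.5e-3,
                         min_correlation = 0.5)
  fwd <- track_pair(v0, v1, cfg)
  bwd <- track_pair(v1, v0, cfg)
  # high-quality windows: both directions confident and unflagged
  both <- fwd$valid & bwd$valid & fwd$quality > 0.7 & bwd$quality > 0.7
  expect_gt(sum(both), 20)
  mismatch <- abs(fwd$d[both] + bwd$d[both])
  expect_lt(median(mismatch), 0.05 * su$grid$axial_step)
  expect_lt(unname(quantile(mismatch, 0.9)), 0.3 * su$grid$axial_step)
})

test_that("window bookkeeping matches the closed-form count", {
  for (n_d in c(100L, 257L, 898L)) for (wlen in c(20L, 92L)) for (hop in c(5L, 9L)) {
    starts <- ewi3d:::window_starts(n_d, wlen, hop)
    expect_identical(length(starts), as.integer(floor((n_d - wlen) / hop) + 1L))
    # brute-force enumeration: every window fits, the next one would not
    expect_true(all(starts + wlen - 1L <= n_d))
    expect_gt(max(starts) + hop + wlen - 1L, n_d)
  }
})

test_that("M-mode extraction has the documented shape and statics are zero", {
  su <- micro_setup(n_elem = 4L, step = 0.2e-3, depth = c(20e-3, 28e-3),
                    lines_per_degree = 0.25)
  set.seed(7)
  cl <- point_cloud(cbind(runif(40, -2e-3, 2e-3), runif(40, -2e-3, 2e-3),
                          runif(40, 21e-3, 27e-3)), rnorm(40))
  chd <- simulate_sequence(cl, su$scheme, su$probe, su$medium, su$pulse,
                           su$fs, 3, grid = su$grid)
  vols <- lapply(1:3, function(k) das_beamform(chd, k, su$grid))
  dser <- track_sequence(vols, tracking_config(window_length = 2e-3,
                                               overlap = 0.5,
                                               max_lag = 0.4e-3), rate = 840)
  mm <- displacement_mmode(dser)
  expect_identical(dim(mm), c(dim(dser$d)[1], 2L))
  expect_equal(max(abs(mm), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("grid mismatch is rejected", {
  su <- micro_setup(n_elem = 4L, step = 0.2e-3, depth = c(20e-3, 28e-3),
                    lines_per_degree = 0.25)
  cl <- point_cloud(c(0, 0, 24e-3))
  chd <- simulate_sequence(cl, su$scheme, su$probe, su$medium, su$pulse,
                           su$fs, 1, grid = su$grid)
  v <- das_beamform(chd, 1, su$grid)
  g2 <- scan_grid(20e-3, 28e-3, 0.2e-3, sector_deg = 16, lines_per_degree = 0.25)
  v2 <- v; v2$grid <- g2
  expect_error(track_pair(v, v2), "grid")
})
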