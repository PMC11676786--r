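test_that("the zero crossing of an analytic cosine is dated to sub-sample accuracy", {
  fs <- 840
  t <- seq(0, 1, by = 1 / fs)
  eps <- cos(2 * pi * t)
  r <- detect_onset(eps, t, ref_time = 0, window = 1)
  expect_identical(r$method, "zero_crossing")
  expect_lt(abs(r$t_act - 0.25), 1e-3)
})

test_that("all-positive curves yield no onset and empty windows error", {
  t <- seq(0, 0.3, by = 1 / 840)
  expect_null(detect_onset(rep(0.01, length(t)), t, 0, 0.3))
  expect_error(detect_onset(rep(0.01, length(t)), t, 1.0, 0.1), "empty")
})

test_that("the rapid-decrease fallback dates the sample before the plunge", {
  fs <- 840
  t <- (seq_len(60) - 1) / fs
  eps <- rep(-0.001, 60)
  eps[37:60] <- -0.001 - 0.02 * seq_len(24)
  r <- detect_onset(eps, t, 0, max(t))
  expect_identical(r$method, "rapid_decrease")
  expect_equal(r$t_act, t[36])
})

test_that("onset detection is invariant to positive rescaling", {
  set.seed(11)
  fs <- 840
  t <- (seq_len(200) - 1) / fs
  eps <- 1e-5 * rnorm(200)
  ramp <- 80:140
  eps[ramp] <- eps[ramp] - 0.003 * seq_along(ramp)
  eps[141:200] <- eps[141:200] - 0.003 * 61
  r1 <- detect_onset(eps, t, 0, max(t))
  r2 <- detect_onset(1e4 * eps, t, 0, max(t))
  r3 <- detect_onset(0.037 * eps, t, 0, max(t))
  expect_false(is.null(r1))
  expect_equal(r1$t_act, r2$t_act)
  expect_equal(r1$t_act, r3$t_act)
  expect_identical(r1$method, r2$method)
})

test_that("the significance gate rejects noise crossings but keeps real onsets", {
  set.seed(12)
  fs <- 840
  n <- 250
  t <- (seq_len(n) - 1) / fs
  noise <- 1e-5 * rnorm(n)
  onset_i <- 120
  eps <- noise
  eps[onset_i:n] <- eps[onset_i:n] - 0.003 * seq_len(n - onset_i + 1)
  r <- detect_onset(eps, t, 0, max(t))
  expect_false(is.null(r))
  # the dated onset is near the true ramp start, not at the first noise flip
  expect_lt(abs(r$t_act - t[onset_i]), 5 / fs)
  # with the gate disabled the literal rule fires on the first noise flip
  r0 <- detect_onset(eps, t, 0, max(t),
                     activation_config(crossing_significance = 0))
  expect_lt(r0$t_act, r$t_act)
})

test_that("scattered interpolation is exact at detection sites", {
  set.seed(13)
  xyz <- cbind(runif(30), runif(30), runif(30)) * 1e-2
  y <- rnorm(30)
  est <- ewi3d:::rbf_interp3(xyz, y, xyz)
  expect_equal(est, y, tolerance = 1e-8)
  # smooth reproduction: affine fields are reproduced exactly
  aff <- 2 + 100 * xyz[, 1] - 50 * xyz[, 3]
  grid_pts <- cbind(runif(40), runif(40), runif(40)) * 1e-2
  est2 <- ewi3d:::rbf_interp3(xyz, aff, grid_pts)
  expect_equal(est2, 2 + 100 * grid_pts[, 1] - 50 * grid_pts[, 3],
               tolerance = 1e-6)
})

synthetic_strain_series <- function(t_act_map, times, rate = 840,
                                    s_rate = -0.003) {
  dims <- dim(t_act_map)
  n_t <- length(times)
  eps <- array(0, c(dims, n_t))
  for (k in seq_len(n_t))
    eps[, , , k][times[k] > t_act_map] <- s_rate
  eps <- eps + 1e-7  # small positive bias so a true crossing exists
  structure(list(eps = eps, valid = array(TRUE, c(dims, n_t)),
                 depths = seq(30e-3, by = 0.5e-3, length.out = dims[1]),
                 grid = NULL, times = times, rate = rate),
            class = "ewi_strain_series")
}

test_that("map_activation recovers a synthetic wave and is seed-deterministic", {
  g <- scan_grid(30e-3, 36e-3, 0.5e-3, az_deg = seq(-3, 3), el_deg = seq(-3, 3))
  co <- grid_coordinates(g)
  dims <- dim(co$x)
  mask <- array(4L, dims)
  origin <- c(co$x[1], co$y[1], co$z[1])
  q0 <- 0.05
  t_true <- q0 + sqrt((co$x - origin[1])^2 + (co$y - origin[2])^2 +
                        (co$z - origin[3])^2) / 1.0
  times <- (seq_len(200) - 0.5) / 840
  sser <- synthetic_strain_series(t_true, times)
  markers <- list(p_onset = 0.01, q_onset = q0)
  cfg <- activation_config(n_sample_voxels = 60L, seed = 21L)
  map <- map_activation(sser, mask, co, markers, cfg)
  # detections are exact at sites up to the sampling interval
  det <- map$detections
  expect_gt(nrow(det), 30)
  err <- det$t_act - t_true[det$site]
  expect_lt(max(abs(err)), 2.5 / 840)
  # interpolation equals detections exactly at detection sites
  expect_equal(map$t_ms[det$site], (det$t_act - q0) * 1e3, tolerance = 1e-9)
  # interpolated voxels carry the interpolated flag
  expect_true(any(map$method == 3L, na.rm = TRUE))
  # determinism: same seed, same sampled voxel set and map
  map2 <- map_activation(sser, mask, co, markers, cfg)
  expect_identical(map$detections$site, map2$detections$site)
  expect_identical(map$t_ms, map2$t_ms)
  # monotone in distance bins
  d <- sqrt((co$x[det$site] - origin[1])^2 + (co$y[det$site] - origin[2])^2 +
              (co$z[det$site] - origin[3])^2)
  bins <- cut(d, 4)
  med <- tapply(det$t_act, bins, median)
  expect_true(all(diff(na.omit(med)) >= 0))
})

test_that("an all-positive strain region warns and stays unset", {
  dims <- c(6L, 3L, 3L)
  g <- scan_grid(30e-3, 33e-3, 0.5e-3, az_deg = -1:1, el_deg = -1:1)
  co <- grid_coordinates(g)
  mask <- array(4L, dims)
  times <- (seq_len(100) - 0.5) / 840
  eps <- array(0.01, c(dims, 100))
  sser <- structure(list(eps = eps, valid = array(TRUE, c(dims, 100)),
                         depths = g$depths, grid = g, times = times, rate = 840),
                    class = "ewi_strain_series")
  expect_warning(
    map <- map_activation(sser, mask, co, list(p_onset = 0.005, q_onset = 0.02),
                          activation_config(n_sample_voxels = 20L)),
    "no activation detected")
  expect_true(all(is.na(map$t_ms)))
})

test_that("activation statistics summarize regions with their references", {
  mask <- array(0L, c(4, 3, 3))
  mask[1:2, , ] <- 4L; mask[3:4, , ] <- 1L
  map <- list(t_ms = array(NA_real_, dim(mask)),
              t_abs_ms = array(NA_real_, dim(mask)))
  map$t_ms[mask == 4L] <- 50
  map$t_abs_ms[mask == 4L] <- 80
  map$t_ms[mask == 1L] <- c(10, 30, rep(20, 16))
  map$t_abs_ms[mask == 1L] <- c(10, 30, rep(20, 16))
  st <- activation_stats(map, mask)
  vent <- st[st$region == "ventricles", ]
  expect_equal(vent$mean_ms, 50)
  expect_equal(vent$span_ms, 0)
  atr <- st[st$region == "atria", ]
  expect_equal(atr$span_ms, 20)
  expect_identical(vent$reference, "q_onset")
  # empty regions are omitted with a warning
  m2 <- array(4L, c(2, 2, 2))
  map2 <- list(t_ms = array(NA_real_, dim(m2)), t_abs_ms = array(NA_real_, dim(m2)))
  map2$t_ms[] <- 5; map2$t_abs_ms[] <- 25
  expect_warning(st2 <- activation_stats(map2, m2), "empty")
  expect_false("atria" %in% st2$region)
})
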