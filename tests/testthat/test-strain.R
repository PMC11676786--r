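test_that("SG gradient is exact on linear fields and zero on constants", {
  z <- seq(0, 50e-3, by = 0.5e-3)
  u <- 0.01 * z
  eps <- sg_gradient(u, 0.5e-3)
  expect_equal(eps, rep(0.01, length(u)), tolerance = 1e-12)
  expect_equal(sg_gradient(rep(0.37, 60), 0.5e-3), rep(0, 60), tolerance = 1e-12)
  expect_error(sg_gradient(c(1, 2), 0.5e-3), "3")
})

test_that("SG gradient equals the explicit windowed least-squares slope", {
  set.seed(8)
  n <- 80L
  spacing <- 0.48e-3
  u <- cumsum(rnorm(n)) * 1e-5
  cfg <- strain_config(sg_window = 3.2e-3)
  h <- ewi3d:::sg_half_width(cfg, spacing)
  eps <- sg_gradient(u, spacing, cfg)
  # interior samples: normal-equations oracle on the centered window
  for (i in c(h + 1L, 25L, n - h)) {
    idx <- (i - h):(i + h)
    fit <- lm(u[idx] ~ I(idx * spacing))
    expect_equal(eps[i], unname(coef(fit)[2]), tolerance = 1e-9)
  }
  # boundary samples: truncated one-sided windows
  for (i in c(1L, 2L, n)) {
    idx <- max(1L, i - h):min(n, i + h)
    fit <- lm(u[idx] ~ I(idx * spacing))
    expect_equal(eps[i], unname(coef(fit)[2]), tolerance = 1e-9)
  }
})

test_that("SG interior weights agree with the signal package convention", {
  skip_if_not_installed("signal")
  set.seed(9)
  n <- 120L; spacing <- 1e-3
  u <- cumsum(rnorm(n)) * 1e-4
  cfg <- strain_config(sg_window = 7e-3)
  h <- ewi3d:::sg_half_width(cfg, spacing)
  ref <- signal::sgolayfilt(u, p = 1, n = 2 * h + 1, m = 1, ts = spacing)
  eps <- sg_gradient(u, spacing, cfg)
  core <- (h + 1):(n - h)
  expect_equal(eps[core], ref[core], tolerance = 1e-9)
})

test_that("the SG operator is linear", {
  set.seed(10)
  a <- rnorm(50); b <- rnorm(50)
  s <- 0.5e-3
  expect_equal(sg_gradient(2 * a + 3 * b, s),
               2 * sg_gradient(a, s) + 3 * sg_gradient(b, s), tolerance = 1e-12)
})

fake_series <- function(d_list, depths, valid = NULL) {
  n <- length(d_list)
  dims <- c(dim(d_list[[1]]), n)
  d <- array(NA_real_, dims)
  for (k in seq_len(n)) d[, , , k] <- d_list[[k]]
  v <- valid %||% array(TRUE, dims)
  ewi3d:::new_displacement_series(d, array(1, dims), v, depths,
                                  scan_grid(depths[1], max(depths) + 1e-3,
                                            depths[2] - depths[1],
                                            az_deg = seq_len(dims[2]),
                                            el_deg = seq_len(dims[3])),
                                  tracking_config(), (seq_len(n) - 0.5) / 840, 840)
}

test_that("accumulation is Eulerian, additive and validity-propagating", {
  depths <- seq(30e-3, 60e-3, by = 0.5e-3)
  nw <- length(depths)
  base <- array(1e-5, c(nw, 3, 3))
  dser <- fake_series(list(base, 2 * base, 3 * base, 4 * base), depths)
  # single step: identity
  one <- accumulate_displacement(dser, 2, 3)
  expect_equal(one$u, 2 * base, tolerance = 1e-15)
  # constant per-step displacement over n steps: n * d
  all4 <- accumulate_displacement(dser, 1, 5)
  expect_equal(all4$u, 10 * base, tolerance = 1e-15)
  # additivity over adjacent intervals is exact
  a <- accumulate_displacement(dser, 1, 3)$u
  b <- accumulate_displacement(dser, 3, 5)$u
  expect_identical(a + b, all4$u)
  expect_error(accumulate_displacement(dser, 3, 3), "k0 < k1")
  # validity propagates through every summed step
  val <- array(TRUE, c(nw, 3, 3, 4)); val[5, 1, 1, 2] <- FALSE
  dser2 <- fake_series(list(base, base, base, base), depths, val)
  expect_false(accumulate_displacement(dser2, 1, 5)$valid[5, 1, 1])
  expect_true(accumulate_displacement(dser2, 3, 5)$valid[5, 1, 1])
})

test_that("Lagrangian accumulation follows material through the lattice", {
  depths <- seq(30e-3, 60e-3, by = 0.5e-3)
  nw <- length(depths)
  # step 1: uniform displacement of 0.6 mm toward the probe (> one lattice
  # step); step 2: a depth-dependent profile
  step1 <- array(0.6e-3, c(nw, 2, 2))
  prof <- seq(0, 1e-3, length.out = nw)
  step2 <- array(rep(prof, 4), c(nw, 2, 2))
  dser <- fake_series(list(step1, step2), depths)
  eul <- accumulate_displacement(dser, 1, 3)
  lag <- accumulate_displacement(dser, 1, 3, lagrangian = TRUE)
  # Eulerian reads the second step at the fixed site ...
  expect_equal(eul$u[, 1, 1], 0.6e-3 + prof, tolerance = 1e-15)
  # ... Lagrangian reads it one lattice sample shallower (material moved
  # toward the probe by round(0.6/0.5) = 1 sample)
  expect_equal(lag$u[3:nw, 1, 1], 0.6e-3 + prof[2:(nw - 1)], tolerance = 1e-15)
  # sites whose material left the lattice are invalidated
  expect_false(lag$valid[1, 1, 1])
  # for sub-sample cumulative motion both modes agree exactly
  small <- array(0.1e-3, c(nw, 2, 2))
  dser2 <- fake_series(list(small, step2), depths)
  expect_identical(accumulate_displacement(dser2, 1, 3)$u,
                   accumulate_displacement(dser2, 1, 3, lagrangian = TRUE)$u)
})

test_that("end-systolic strain recovers a prescribed uniform gradient", {
  depths <- seq(30e-3, 60e-3, by = 0.5e-3)
  nw <- length(depths)
  # toward-transducer displacement growing with depth = shortening
  u <- array(rep(0.1 * (depths - depths[1]), 9), c(nw, 3, 3))
  cum <- structure(list(u = u, valid = array(TRUE, c(nw, 3, 3)), k0 = 1, k1 = 2,
                        depths = depths, grid = NULL), class = "ewi_cumulative")
  es <- end_systolic_strain(cum)
  expect_equal(as.vector(es$eps), rep(-0.1, length(es$eps)), tolerance = 1e-12)
  # zero cumulative field -> zero strain
  cum$u[] <- 0
  expect_equal(max(abs(end_systolic_strain(cum)$eps)), 0, tolerance = 1e-15)
})

test_that("strain of accumulated linear fields equals the sum of per-step strains", {
  depths <- seq(30e-3, 50e-3, by = 0.5e-3)
  nw <- length(depths)
  mk <- function(s) array(rep(s * (depths - depths[1]), 4), c(nw, 2, 2))
  dser <- fake_series(list(mk(0.01), mk(0.02), mk(0.03)), depths)
  sser <- inter_volume_strain(dser)
  cum <- accumulate_displacement(dser, 1, 4)
  es <- end_systolic_strain(cum)
  per_step_sum <- sser$eps[, , , 1] + sser$eps[, , , 2] + sser$eps[, , , 3]
  expect_equal(es$eps, per_step_sum, tolerance = 1e-12)
  # sign convention: positive (toward-transducer) displacement growing with
  # depth is longitudinal shortening
  expect_lt(max(es$eps), 0)
})
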