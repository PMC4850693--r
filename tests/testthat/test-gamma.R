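test_that("pulses are binned to control points by planned cumulative MU", {
  tr <- wave_trajectory(c(0, 24), c(0, 0))
  cp <- build_control_points(discretize_beams(tr))
  pl <- delivery_plan(cp, c(10, 30, 5, 5))  # boundaries at 10, 40, 45, 50
  pulses <- data.frame(mu = rep(1, 50), reading = rep(0.002, 50))
  per_cp <- bin_pulses_to_cps(pulses, pl)
  expect_equal(per_cp, c(10, 30, 5, 5) * 0.002)

  # a pulse straddling a boundary is split pro-rata
  pl2 <- delivery_plan(cp, c(10, 10, 10, 10))
  pulses2 <- data.frame(mu = c(8, 4, 28), reading = c(8, 4, 28))
  expect_equal(bin_pulses_to_cps(pulses2, pl2), c(10, 10, 10, 10))

  # single-CP degenerate arc: everything lands in it
  one <- pl; one$cp <- pl$cp[1, , drop = FALSE]; one$total_mu <- 50
  one$cp$mu_weight <- 50
  expect_equal(bin_pulses_to_cps(pulses, one), 0.1)

  bad <- data.frame(mu = rep(1, 40), reading = rep(1, 40))
  expect_error(bin_pulses_to_cps(bad, pl), "1%")
})

test_that("angular corrections weight per-CP dose multiplicatively", {
  tr <- wave_trajectory(c(0, 24), c(0, 0))
  cp <- build_control_points(discretize_beams(tr))
  pl <- delivery_plan(cp, rep(1, 4))
  d <- matrix(1, nrow = 3, ncol = 4)
  expect_equal(apply_angular_corrections(d, pl), rowSums(d))
  const <- function(g, r, p) 1.02
  expect_equal(apply_angular_corrections(d, pl, const), rowSums(d) * 1.02)
  # two CPs with factors {1, 0.5} and equal dose d: 0.75 * 2d
  pl2 <- pl; pl2$cp <- pl$cp[1:2, ]
  half_second <- function(g, r, p) if (g > 3) 0.5 else 1  # CP2 at g = 6
  d2 <- matrix(2, nrow = 1, ncol = 2)
  expect_equal(apply_angular_corrections(d2, pl2, half_second), 3)
  neg <- function(g, r, p) -1
  expect_error(apply_angular_corrections(d, pl, neg), "positive")
  # collapsing ring to 0 in a ring-only model is the coplanar QA mapping
  ring_model <- cosine_correction(0.1)
  pl0 <- pl; pl0$cp$ring <- 0
  expect_equal(apply_angular_corrections(d, pl0, ring_model),
               apply_angular_corrections(d, pl))
})

test_that("identical measurement gives gamma 0 and full passing rate", {
  g <- gaussian_grid()
  dio <- default_diode_geometry(g, pitch = 25)
  m <- perturb_measurement(g, dio)
  res <- gamma_min3d(m, g)
  expect_true(all(res$gamma < 1e-12))
  expect_equal(passing_rate(res), 100)
})

test_that("a flat +3%-of-max offset sits exactly on the gamma boundary", {
  sh <- c(11, 11, 11)
  flat <- dose_grid(array(1, dim = sh), origin = c(-25, -25, -25),
                    spacing = c(5, 5, 5))
  dio <- default_diode_geometry(flat, pitch = 15)
  m <- perturb_measurement(flat, dio, scale_pct = 3)
  res <- gamma_min3d(m, flat)
  expect_equal(res$gamma, rep(1, nrow(res)), tolerance = 1e-12)
  expect_equal(passing_rate(res), 100)  # gamma exactly 1 counts as passing
})

test_that("a 3 mm rigid shift of a smooth field passes 3%/3mm everywhere", {
  g <- gaussian_grid()
  dio <- default_diode_geometry(g, pitch = 25)
  m <- perturb_measurement(g, dio, shift_mm = c(3, 0, 0))
  res <- gamma_min3d(m, g)
  expect_true(all(res$gamma <= 1 + 1e-9))
  expect_equal(passing_rate(res), 100)
})

test_that("optimized search equals exhaustive search on small grids", {
  g <- gaussian_grid(shape = c(15, 15, 15), spacing = c(6, 6, 6))
  dio <- default_diode_geometry(g, pitch = 30)
  m <- perturb_measurement(g, dio, scale_pct = 2, noise_sd_pct = 1,
                          seed = 4)
  fast <- gamma_min3d(m, g)
  full <- gamma_min3d(m, g, exhaustive = TRUE)
  expect_equal(fast$gamma, full$gamma, tolerance = 1e-9)
  # voxel-only brute force bounds the candidate-set minimum from above
  dd <- 0.03 * max(g$values)
  for (i in seq_len(min(4, nrow(fast)))) {
    vox <- oracle_gamma_voxels_only(g, c(fast$x[i], fast$y[i], fast$z[i]),
                                    fast$dose[i], dd, 3)
    expect_lte(fast$gamma[i], vox + 1e-12)
  }
})

test_that("global normalization makes gamma scale invariant", {
  g <- gaussian_grid(shape = c(13, 13, 13), spacing = c(6, 6, 6))
  dio <- default_diode_geometry(g, pitch = 30)
  m <- perturb_measurement(g, dio, scale_pct = 2.5)
  r1 <- gamma_min3d(m, g)
  c_scale <- 4.7
  g2 <- dose_grid(g$values * c_scale, g$origin, g$spacing)
  m2 <- diode_plane_set(m$x, m$y, m$z, m$dose * c_scale, m$plane)
  r2 <- gamma_min3d(m2, g2)
  expect_equal(r1$gamma, r2$gamma, tolerance = 1e-9)
})

test_that("gamma is bounded by its pure-dose and pure-distance parts", {
  g <- gaussian_grid(shape = c(13, 13, 13), spacing = c(6, 6, 6))
  dio <- default_diode_geometry(g, pitch = 30)
  m <- perturb_measurement(g, dio, scale_pct = 2, seed = 2)
  res <- gamma_min3d(m, g)
  dd <- 0.03 * max(g$values)
  # the diode's own position is in the candidate set, so gamma never
  # exceeds the pure dose-difference term there
  pt_dose <- interp_dose(g, cbind(res$x, res$y, res$z))
  expect_true(all(res$gamma <= abs(res$dose - pt_dose) / dd + 1e-12))
})

test_that("diodes below the 20% threshold are excluded from the rate", {
  g <- gaussian_grid()  # dose falls well below 20% of max at the edges
  dio <- default_diode_geometry(g, pitch = 20)
  m <- perturb_measurement(g, dio)
  res <- gamma_min3d(m, g)
  expect_lt(attr(res, "evaluated_count"), nrow(m))
  expect_true(all(res$dose >= 0.2 * max(g$values)))
  low <- diode_plane_set(0, 0, 0, dose = 0.01, plane = "xz")
  expect_error(gamma_min3d(low, g), "threshold")
})
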