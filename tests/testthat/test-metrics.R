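make_grid <- function(vals, dim3 = c(5, 5, 4)) {
  dose_grid(array(vals, dim = dim3), origin = c(0, 0, 0),
            spacing = c(10, 10, 10))
}

test_that("coverage is the PTV fraction at or above prescription", {
  g <- make_grid(rep(60, 100))
  ptv <- structure_mask(array(rep(c(TRUE, FALSE), 50), dim = c(5, 5, 4)), g)
  expect_equal(coverage_ratio(ptv, g, 60), 1)  # closed >= convention
  v <- rep(60, 100); v[1:10] <- 10
  g2 <- make_grid(v)
  all_ptv <- structure_mask(array(TRUE, dim = c(5, 5, 4)), g2)
  expect_equal(coverage_ratio(all_ptv, g2, 60), 0.9)
  empty <- structure_mask(array(FALSE, dim = c(5, 5, 4)), g)
  expect_error(coverage_ratio(empty, g, 60), "empty")
})

test_that("low-dose spillage ratios the half-prescription volume to PTV", {
  v <- numeric(100); v[1:40] <- 35; v[41:50] <- 60
  g <- make_grid(v)
  m <- array(FALSE, dim = c(5, 5, 4)); m[41:50] <- TRUE  # PTV = hot 10
  ptv <- structure_mask(m, g)
  expect_equal(low_dose_spillage(ptv, g, 60), 5)  # 50 voxels >= 30 Gy
  expect_equal(low_dose_spillage(ptv, g, 200), 0)
  # invariance under joint dose/prescription rescaling
  g2 <- dose_grid(g$values * 3, g$origin, g$spacing)
  expect_equal(low_dose_spillage(ptv, g2, 180),
               low_dose_spillage(ptv, g, 60))
  expect_equal(coverage_ratio(ptv, g2, 180), coverage_ratio(ptv, g, 60))
})

test_that("DVH points follow the hottest-x% and V_xGy conventions", {
  g <- make_grid(1:100)  # doses 1..100 Gy
  all <- structure_mask(array(TRUE, dim = c(5, 5, 4)), g)
  expect_equal(dvh_point(all, g, "D%", value = 2), 99)
  expect_equal(dvh_point(all, g, "VGy", value = 50),
               51 * all$voxel_volume_cc)
  expect_equal(dvh_point(all, g, "V%", value = 50), 51)
  expect_equal(dvh_point(all, g, "Dmean"), mean(1:100))
  u <- make_grid(rep(42, 100))
  for (x in c(1, 2, 50, 98, 100))
    expect_equal(dvh_point(all, u, "D%", value = x), 42)
  expect_error(dvh_point(all, g, "D%", value = 0), "\\(0, 100\\]")
})

test_that("DVH monotonicity and near-max ordering hold on random doses", {
  set.seed(8)
  for (rep in 1:5) {
    g <- make_grid(stats::rgamma(100, 3, 0.1))
    all <- structure_mask(array(TRUE, dim = c(5, 5, 4)), g)
    dx <- sapply(c(1, 2, 5, 20, 50, 90), function(x)
      dvh_point(all, g, "D%", value = x))
    expect_true(all(diff(dx) <= 1e-12))  # D_x% non-increasing in x
    vx <- sapply(c(5, 10, 20, 40), function(x)
      dvh_point(all, g, "VGy", value = x))
    expect_true(all(diff(vx) <= 1e-12))  # V_xGy non-increasing in x
    d2 <- dvh_point(all, g, "D%", value = 2)
    expect_lte(d2, max(g$values))
    expect_gte(d2, dvh_point(all, g, "Dmean"))
    # brute-force sort oracle for D_2% on 100 voxels: second-hottest voxel
    expect_equal(d2, sort(g$values, decreasing = TRUE)[2])
  }
})

test_that("percent change reproduces the benchmark table arithmetic", {
  expect_equal(percent_change(5.47, 3.44, "reduction"), 37.11152,
               tolerance = 1e-6)
  expect_equal(percent_change(5.47, 3.44, "reduction", report = TRUE), 37)
  expect_equal(percent_change(975, 1370, "increase", report = TRUE), 41)
  expect_equal(percent_change(7, 7, "reduction"), 0)
  expect_error(percent_change(0, 5, "reduction"), "positive")
})

test_that("paired t-test matches the hand-computed fixture and guards", {
  res <- paired_t_test(c(1, 2, 3, 4), c(2, 3, 5, 6))
  # differences {-1,-1,-2,-2}: mean -1.5, sd 0.5774, t = -5.196
  expect_equal(res$t, -1.5 / (sd(c(1, 1, 2, 2)) / 2), tolerance = 1e-12)
  expect_equal(res$t, -5.196152, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_equal(res$p, 0.0138457, tolerance = 1e-4)
  expect_true(res$significant)
  expect_error(paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
  expect_error(paired_t_test(1:3, 1:3), "zero variance")
})

test_that("plan metrics report bundles coverage, spillage and DVH points", {
  v <- numeric(100); v[1:40] <- 35; v[41:50] <- 60
  g <- make_grid(v)
  m <- array(FALSE, dim = c(5, 5, 4)); m[41:50] <- TRUE
  ptv <- structure_mask(m, g)
  rep <- plan_metrics_report(ptv, g, prescription = 60, mu = 495,
                             time_min = 3.09,
                             dvh_queries = list(D2 = list(query = "D%",
                                                          value = 2)))
  expect_equal(rep$coverage, 1)
  expect_equal(rep$low_dose_spillage, 5)
  expect_equal(rep$dvh$D2, 60)
  expect_output(print(rep), "spillage")
})
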