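test_that("identity error model reproduces the planned dose bit-for-bit", {
  err0 <- error_model(blur_sigma = 0, shift = c(0, 0), calib_amp = 0,
                      noise_sd = 0)
  cs <- make_case(phantom_spec(32), err0, seed = 100)
  expect_identical(cs$mdose, cs$rtdose)
})

test_that("planned dose is normalized and confined to the body", {
  cs <- make_case(phantom_spec(c(32, 48)), error_model(), seed = 101)
  expect_identical(max(cs$rtdose), 1)
  b <- phantom_spec(c(32, 48))$body
  Y <- matrix(seq_len(32), 32, 48)
  X <- matrix(seq_len(48), 32, 48, byrow = TRUE)
  outside <- ((X - b$cx) / b$rx)^2 + ((Y - b$cy) / b$ry)^2 > 1
  expect_true(all(cs$rtdose[outside] == 0))
  expect_true(all(cs$mdose >= 0))
  expect_identical(dim(cs$ct), dim(cs$rtdose))
  # reproducibility
  expect_identical(cs$mdose, make_case(phantom_spec(c(32, 48)), error_model(),
                                       seed = 101)$mdose)
})

test_that("blur matches an independent Gaussian-filter oracle", {
  # frozen reference: scipy.ndimage.gaussian_filter(x, 2.0, mode='reflect',
  # truncate=4.0) on the seed-12 uniform field
  withr::with_seed(12, x <- matrix(runif(24 * 24), 24, 24))
  g <- scoredose:::gaussian_blur(x, 2.0)
  expect_equal(mean(g), 0.4955726004635735, tolerance = 1e-10)
  frozen <- c(0.42075145968986283, 0.5198794541410714, 0.5055759781792062,
              0.5187823075303337, 0.45145561282981617)
  got <- c(g[1, 1], g[6, 8], g[12, 12], g[24, 24], g[18, 4])
  expect_equal(got, frozen, tolerance = 1e-10)
  # blur-only error model equals the oracle applied to the planned dose
  cs <- make_case(phantom_spec(32),
                  error_model(blur_sigma = 2, shift = c(0, 0),
                              calib_amp = 0, noise_sd = 0), seed = 7)
  expect_equal(cs$mdose, scoredose:::gaussian_blur(cs$rtdose, 2),
               tolerance = 1e-12)
})

test_that("sub-pixel shift is exact on fields where bilinear is exact", {
  # a plane a + b*i + c*j is reproduced exactly by bilinear interpolation
  H <- 12
  plane <- outer(seq_len(H), seq_len(H), function(i, j) 0.2 + 0.03 * i + 0.01 * j)
  sh <- scoredose:::shift_bilinear(plane, c(0.5, 0.25))
  expected <- outer(seq_len(H), seq_len(H),
                    function(i, j) 0.2 + 0.03 * (i - 0.5) + 0.01 * (j - 0.25))
  interior <- 2:(H - 1)
  expect_equal(sh[interior, interior], expected[interior, interior],
               tolerance = 1e-12)
  expect_identical(scoredose:::shift_bilinear(plane, c(0, 0)), plane)
})

test_that("phantom and error-model invariants are enforced", {
  expect_error(error_model(calib_amp = 0.3), "a")
  expect_error(error_model(blur_sigma = -1), "blur")
  expect_error(phantom_spec(n_targets = 0), "n_targets")
  expect_error(phantom_spec(body = list(cx = 16, cy = 16, rx = 40, ry = 4)),
               "fit inside")
  expect_error(phantom_spec(n_targets = 1,
                            target_centers = matrix(c(1, 1), 1)),
               "outside")
})

test_that("cohort split is exact, stratified, disjoint and reproducible", {
  ds <- make_dataset(300, 0.8, phantom_spec(32), error_model(), seed = 200)
  expect_identical(length(ds$train$cases), 240L)
  expect_identical(length(ds$test$cases), 60L)
  tr_ids <- vapply(ds$train$cases, function(cs) cs$case_id, "")
  te_ids <- vapply(ds$test$cases, function(cs) cs$case_id, "")
  expect_length(intersect(tr_ids, te_ids), 0L)
  expect_setequal(c(tr_ids, te_ids), sprintf("case_%04d", 1:300))
  # per-site train fraction within one case of the global ratio
  tr_sites <- table(vapply(ds$train$cases, function(cs) cs$site, ""))
  all_sites <- table(c(vapply(ds$train$cases, function(cs) cs$site, ""),
                       vapply(ds$test$cases, function(cs) cs$site, "")))
  for (st in names(all_sites)) {
    expect_lte(abs(tr_sites[[st]] - 0.8 * all_sites[[st]]), 1)
  }
  ds2 <- make_dataset(300, 0.8, phantom_spec(32), error_model(), seed = 200)
  expect_identical(ds$manifest$train_ids, ds2$manifest$train_ids)
  expect_identical(ds$train$cases[[1]]$mdose, ds2$train$cases[[1]]$mdose)
  # tiny cohort
  ds5 <- make_dataset(5, 0.8, phantom_spec(32), error_model(), seed = 201)
  expect_identical(length(ds5$train$cases), 4L)
  expect_identical(length(ds5$test$cases), 1L)
  expect_error(make_dataset(10, 0.01), "empty split")
})

test_that("a zero error model yields perfect downstream metrics", {
  err0 <- error_model(blur_sigma = 0, shift = c(0, 0), calib_amp = 0,
                      noise_sd = 0)
  ds <- make_dataset(6, 0.5, phantom_spec(32), err0, seed = 202)
  base <- planned_vs_measured(ds$test)
  expect_true(all(base$ssim == 1))
  expect_true(all(base$mae_pct == 0))
  expect_true(all(base$rmse_pct == 0))
})
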