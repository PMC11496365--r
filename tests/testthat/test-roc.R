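test_that("the ROC corners yield exactly zero savings", {
  map <- delta_map(fig10_config(), fpr_grid = c(0, 1), tpr_grid = c(0, 1))
  corner00 <- map$delta_w_d[map$fpr == 0 & map$tpr == 0]
  corner11 <- map$delta_w_d[map$fpr == 1 & map$tpr == 1]
  expect_lt(abs(corner00), 1e-6)
  expect_lt(abs(corner11), 1e-6)
  expect_true(all(map$status == "ok"))
})

test_that("the map reproduces the headline cell and is order-independent", {
  cfg <- fig10_config()
  map <- delta_map(cfg, fpr_grid = 0.11, tpr_grid = 0.95)
  expect_equal(map$delta_w_d, -35.7955, tolerance = 1e-4)
  fwd <- delta_map(cfg, fpr_grid = c(0.1, 0.3), tpr_grid = c(0.5, 0.9))
  rev <- delta_map(cfg, fpr_grid = c(0.3, 0.1), tpr_grid = c(0.9, 0.5))
  merged <- dplyr::inner_join(tibble::as_tibble(fwd), tibble::as_tibble(rev),
                              by = c("fpr", "tpr"))
  expect_equal(merged$delta_w_d.x, merged$delta_w_d.y, tolerance = 1e-12)
})

test_that("more true positives never reduce the savings at fixed FPR", {
  grid <- seq(0, 1, by = 0.1)
  map <- delta_map(fig10_config(), fpr_grid = grid, tpr_grid = grid)
  for (f1 in grid) {
    col <- map[map$fpr == f1, ]
    col <- col[order(col$tpr), ]
    expect_true(all(diff(col$delta_w_d) <= 1e-9))
  }
})

test_that("savings grow with clinic load and shrink with staffing", {
  rhos <- seq(0.3, 0.8, by = 0.1)
  d1 <- vapply(rhos, function(rho) {
    evaluate_cadt(fig10_config(rho = rho))$delta_w_d
  }, numeric(1))
  expect_true(all(diff(abs(d1)) >= -1e-9))
  # same per-radiologist load, two radiologists: smaller savings
  d2 <- evaluate_cadt(fig10_config(rho = 0.8, n_rad = 2))$delta_w_d
  expect_gte(abs(d1[length(d1)]), abs(d2))
})

test_that("slow non-diseased reads amplify the savings", {
  d_slow <- evaluate_cadt(fig10_config(rt_d = 10, rt_nd = 15))$delta_w_d
  d_fast <- evaluate_cadt(fig10_config(rt_d = 10, rt_nd = 5))$delta_w_d
  expect_gt(abs(d_slow), abs(d_fast))
})

test_that("random triage along the chance line cannot hurt the diseased", {
  cv <- delta_along_curve(fig10_config(), curve = function(x) x,
                          n_points = 9)
  # under equal read rates random triage leaves the diseased mixture wait
  # unchanged, so the delta is zero up to solver precision
  expect_true(all(cv$delta_w_d <= 1e-6))
  expect_lt(abs(cv$delta_w_d[1]), 1e-6)
  expect_lt(abs(cv$delta_w_d[nrow(cv)]), 1e-6)
})

test_that("curve endpoints coincide with the map corners", {
  cfg <- fig10_config()
  cv <- delta_along_curve(cfg, curve = binormal_curve(0.9), n_points = 5)
  map <- delta_map(cfg, fpr_grid = c(0, 1), tpr_grid = c(0, 1))
  expect_equal(cv$delta_w_d[1],
               map$delta_w_d[map$fpr == 0 & map$tpr == 0], tolerance = 1e-9)
  expect_equal(cv$delta_w_d[5],
               map$delta_w_d[map$fpr == 1 & map$tpr == 1], tolerance = 1e-9)
  # a degenerate all-positive curve ends at zero savings
  cv1 <- delta_along_curve(cfg, curve = function(x) 1, n_points = 3)
  expect_lt(abs(cv1$delta_w_d[3]), 1e-6)
  expect_error(delta_along_curve(cfg, curve = function(x) 1 - x),
               "monotone")
})

test_that("time savings translate linearly into stroke outcomes", {
  expect_equal(stroke_outcome_scaling(-15), 3.9)
  expect_equal(stroke_outcome_scaling(0), 0)
  expect_equal(stroke_outcome_scaling(-36), 9.36)
  expect_equal(stroke_outcome_scaling(10), 0)   # delays clamp to zero
  expect_equal(stroke_outcome_scaling(-30), 2 * stroke_outcome_scaling(-15))
})

test_that("plot builders return ggplot objects", {
  map <- delta_map(fig10_config(), fpr_grid = c(0, 0.5, 1),
                   tpr_grid = c(0, 0.5, 1))
  expect_s3_class(autoplot(map), "ggplot")
  sim <- run_batch(fig10_config(rho = 0.5), n_runs = 8,
                   patients_per_run = 150, seed = 1)
  expect_s3_class(autoplot(sim), "ggplot")
  cv <- delta_along_curve(fig10_config(), n_points = 5)
  expect_s3_class(plot_delta_curve(cv), "ggplot")
})
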