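test_that("paired worlds share arrivals and durations, diverging only by discipline", {
  # with no positives and no interruptions both worlds are FIFO: identical
  cfg0 <- fig10_config(se = 0, sp = 1)
  rec <- simulate_run(cfg0, n_patients = 500, seed = 3)
  expect_identical(rec$wait_without, rec$wait_with)
  # waits are never negative (total service equals the sampled duration)
  cfg <- fig10_config(f = 0.3, se = 0.9, sp = 0.85, n_rad = 2)
  rec2 <- simulate_run(cfg, n_patients = 1000, seed = 4)
  expect_true(all(rec2$wait_without > -1e-9))
  expect_true(all(rec2$wait_with > -1e-9))
  # identical draws, different discipline: the diseased gain, on average
  expect_lt(mean(rec2$wait_with[rec2$is_diseased]),
            mean(rec2$wait_without[rec2$is_diseased]))
})

test_that("thinning reproduces the class mix within binomial error", {
  cfg <- fig10_config(f = 0.3, se = 0.9, sp = 0.85)
  r <- derive_rates(cfg)
  n <- 4000
  rec <- simulate_run(cfg, n_patients = n, seed = 12)
  p <- c(f = 0.3,
         pos = (1 - 0.3) * r$lambda_pos / r$lambda_nonf,
         neg = (1 - 0.3) * r$lambda_neg / r$lambda_nonf)
  obs <- c(mean(rec$is_interrupting), mean(rec$ai_positive),
           mean(!rec$is_interrupting & !rec$ai_positive))
  for (i in 1:3) {
    expect_lt(abs(obs[i] - p[i]), 3 * sqrt(p[i] * (1 - p[i]) / n))
  }
  # empirical arrival rate
  lam <- lambda_from_rho(cfg)
  lam_hat <- n / max(rec$arrival_time)
  expect_lt(abs(lam_hat - lam), 3 * lam / sqrt(n))
})

test_that("runs are reproducible and child streams are isolated", {
  cfg <- fig10_config()
  a <- simulate_run(cfg, 200, seed = 9)
  b <- simulate_run(cfg, 200, seed = 9)
  expect_identical(a, b)
  s2 <- run_batch(cfg, n_runs = 2, patients_per_run = 150, seed = 5)
  s5 <- run_batch(cfg, n_runs = 5, patients_per_run = 150, seed = 5)
  expect_identical(s2$per_run[1:2, ], s5$per_run[1:2, ])
})

test_that("pre-arrival census matches the stationary distribution (PASTA)", {
  cfg <- fig10_config(se = 0, sp = 1)     # plain M/M/1 in both worlds
  nrun <- 12
  recs <- dplyr::bind_rows(lapply(seq_len(nrun), function(r) {
    simulate_run(cfg, 1500, seed = 100 + r)
  }))
  dist <- state_census_distribution(recs, "census_without_nonf")
  expect_equal(sum(dist$probability), 1, tolerance = 1e-12)
  # p0 within Monte-Carlo error of 1 - rho (per-run spread gives the SE)
  p0_runs <- vapply(seq_len(nrun), function(r) {
    d <- simulate_run(cfg, 1500, seed = 100 + r)
    mean(d$census_without_nonf == 0)
  }, numeric(1))
  se0 <- sd(p0_runs) / sqrt(nrun)
  expect_lt(abs(mean(p0_runs) - 0.2), 3 * se0 + 0.01)
  # mean pre-arrival count against the chain's L (autocorrelation-aware SE)
  L_runs <- vapply(seq_len(nrun), function(r) {
    d <- simulate_run(cfg, 1500, seed = 100 + r)
    mean(d$census_without_nonf)
  }, numeric(1))
  L_theory <- mean_number_in_class(
    solve_qbd(build_model1_without_cadt(derive_rates(cfg)))$dist
  )
  expect_lt(abs(mean(L_runs) - L_theory), 3 * sd(L_runs) / sqrt(nrun))
})

test_that("batch summaries bracket the theoretical saving", {
  cfg <- fig10_config()
  sim <- run_batch(cfg, n_runs = 30, patients_per_run = 800, seed = 21)
  s <- sim$summary
  expect_lte(s$delta_w_d_lo, s$delta_w_d)
  expect_lte(s$delta_w_d, s$delta_w_d_hi)
  th <- evaluate_cadt(cfg)$delta_w_d
  expect_gt(th, s$delta_w_d_lo)
  expect_lt(th, s$delta_w_d_hi)
  expect_equal(nrow(tidy(sim)), 30)
})

test_that("confidence intervals narrow like one over root runs", {
  cfg <- fig10_config(rho = 0.6)
  s1 <- run_batch(cfg, n_runs = 80, patients_per_run = 200, seed = 2)
  s2 <- run_batch(cfg, n_runs = 320, patients_per_run = 200, seed = 2)
  w1 <- s1$summary$delta_w_d_hi_norm - s1$summary$delta_w_d_lo_norm
  w2 <- s2$summary$delta_w_d_hi_norm - s2$summary$delta_w_d_lo_norm
  expect_equal(w1 / w2, 2, tolerance = 0.2)
})
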