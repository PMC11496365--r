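test_that("without-CADt waits match M/M/1, Erlang-C and Pollaczek-Khinchine", {
  # M/M/1 across the load range
  for (rho in seq(0.1, 0.9, by = 0.1)) {
    cfg <- fig10_config(rho = rho)
    w <- solve_qbd(build_model1_without_cadt(derive_rates(cfg)))$wait
    expect_equal(w$w_queue, mm1_wq(rho * 0.1, 0.1), tolerance = 1e-8)
  }
  # Erlang-C with two radiologists
  cfg2 <- fig10_config(n_rad = 2)
  w2 <- solve_qbd(build_model1_without_cadt(derive_rates(cfg2)))$wait
  expect_equal(w2$w_queue, mmc_wq(0.16, 0.1, 2), tolerance = 1e-8)
  expect_equal(w2$w_queue, 17.7778, tolerance = 1e-4)
  # hyperexponential M/G/1 (unequal read rates, one radiologist)
  cfgpk <- workflow_config(prevalence = 0.1, se = 0.95, sp = 0.89, f = 0,
                           n_rad = 1, read_time_diseased = 10,
                           read_time_nondiseased = 15, lambda = 0.05)
  wpk <- solve_qbd(build_model2_without_cadt(derive_rates(cfgpk)))$wait
  s1 <- 0.1 * 10 + 0.9 * 15
  s2 <- 0.1 * 200 + 0.9 * 450
  expect_equal(wpk$w_queue, pk_wq(0.05, s1, s2), tolerance = 1e-8)
  expect_equal(wpk$w_queue, 38.6364, tolerance = 1e-4)
})

test_that("with-CADt waits match the preemptive-resume priority closed forms", {
  cfg <- fig10_config()
  r <- derive_rates(cfg)
  w <- compute_waits(cfg)
  lam <- c(r$lambda_pos, r$lambda_neg)
  mu <- c(r$mu_pos, r$mu_neg)
  expect_equal(w$w_queue[w$class == "pos"], preemptive_wq(lam, mu, 1),
               tolerance = 1e-6)
  expect_equal(w$w_queue[w$class == "neg"], preemptive_wq(lam, mu, 2),
               tolerance = 1e-6)
  expect_equal(w$w_queue[w$class == "pos"], 1.837121, tolerance = 1e-6)
  expect_equal(w$w_queue[w$class == "neg"], 49.185606, tolerance = 1e-6)

  # with interrupting images: three-class preemptive closed form
  cfg_f <- fig10_config(f = 0.5)
  rf <- derive_rates(cfg_f)
  wf <- compute_waits(cfg_f)
  lam3 <- c(rf$lambda_f, rf$lambda_pos, rf$lambda_neg)
  mu3 <- c(rf$mu_f, rf$mu_pos, rf$mu_neg)
  expect_equal(wf$w_queue[wf$class == "nonf"],
               preemptive_wq(c(rf$lambda_f, rf$lambda_nonf),
                             c(rf$mu_f, rf$mu_nonf), 2), tolerance = 1e-6)
  expect_equal(wf$w_queue[wf$class == "pos"], preemptive_wq(lam3, mu3, 2),
               tolerance = 1e-6)
  expect_equal(wf$w_queue[wf$class == "neg"], preemptive_wq(lam3, mu3, 3),
               tolerance = 1e-6)
})

test_that("degenerate operating points collapse the with-CADt chains", {
  # everything AI-positive: the positive chain is the without-CADt chain
  cfg_all_pos <- fig10_config(se = 1, sp = 0)
  w <- compute_waits(cfg_all_pos)
  expect_equal(w$w_queue[w$class == "pos"], w$w_queue[w$class == "nonf"],
               tolerance = 1e-9)
  expect_equal(w$w_queue[w$class == "neg"], 0)
  # everything AI-negative: no prioritization at all
  cfg_all_neg <- fig10_config(se = 0, sp = 1)
  w0 <- compute_waits(cfg_all_neg)
  expect_equal(w0$w_queue[w0$class == "neg"], w0$w_queue[w0$class == "nonf"],
               tolerance = 1e-9)
  expect_equal(w0$w_queue[w0$class == "pos"], 0)
})

test_that("the two workflow models agree when read rates coincide", {
  grid <- expand.grid(rho = c(0.4, 0.6, 0.8), pi = c(0.05, 0.1, 0.3),
                      op = 1:3)
  ops <- list(c(0.8, 0.8), c(0.95, 0.89), c(0.6, 0.95))
  for (g in seq_len(nrow(grid))) {
    op <- ops[[grid$op[g]]]
    cfg <- workflow_config(prevalence = grid$pi[g], se = op[1], sp = op[2],
                           f = 0.2, n_rad = 1, read_time_interrupting = 5,
                           read_time_diseased = 10,
                           read_time_nondiseased = 10, rho = grid$rho[g])
    w1 <- compute_waits(cfg, model = "1")
    w2 <- compute_waits(cfg, model = "2")
    expect_equal(w2$w_queue, w1$w_queue, tolerance = 1e-6)
  }
})

test_that("work is conserved across the AI split under equal service", {
  grid <- expand.grid(rho = c(0.3, 0.6, 0.85), pi = c(0.05, 0.1, 0.3),
                      op = 1:3)
  ops <- list(c(0.8, 0.8), c(0.95, 0.89), c(0.6, 0.95))
  for (g in seq_len(nrow(grid))) {
    op <- ops[[grid$op[g]]]
    cfg <- fig10_config(se = op[1], sp = op[2], rho = grid$rho[g])
    cfg$prevalence <- grid$pi[g]
    r <- derive_rates(cfg)
    w <- compute_waits(cfg)
    lhs <- r$lambda_pos * w$w_queue[w$class == "pos"] +
      r$lambda_neg * w$w_queue[w$class == "neg"]
    rhs <- r$lambda_nonf * w$w_queue[w$class == "nonf"]
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
  # the numbers at the headline operating point
  cfg <- fig10_config()
  r <- derive_rates(cfg)
  w <- compute_waits(cfg)
  expect_equal(r$lambda_pos * w$w_queue[2] + r$lambda_neg * w$w_queue[3],
               3.2, tolerance = 1e-6)
})

test_that("prioritized classes wait no longer than deprioritized ones", {
  set.seed(8)
  for (i in 1:10) {
    cfg <- workflow_config(
      prevalence = runif(1, 0.05, 0.4), se = runif(1, 0.3, 0.99),
      sp = runif(1, 0.3, 0.99), f = runif(1, 0, 0.4),
      n_rad = sample(1:2, 1), read_time_interrupting = 5,
      read_time_diseased = 10, read_time_nondiseased = 10,
      rho = runif(1, 0.3, 0.85)
    )
    w <- compute_waits(cfg)
    expect_lte(w$w_queue[w$class == "pos"],
               w$w_queue[w$class == "nonf"] + 1e-9)
    expect_lte(w$w_queue[w$class == "nonf"],
               w$w_queue[w$class == "neg"] + 1e-9)
  }
})

test_that("disease-status memory routes busy periods back to the right image", {
  rates <- derive_rates(workflow_config(
    prevalence = 0.2, se = 0.9, sp = 0.85, f = 0.3, n_rad = 1,
    read_time_diseased = 12, read_time_nondiseased = 8, rho = 0.7
  ))
  ch <- build_model2_without_cadt(rates)
  lab <- ch$phase_labels
  bpD <- grepl("^bpD", lab)
  bpND <- grepl("^bpND", lab)
  # interruption phases that must resume a diseased image never flow into
  # the non-diseased service phase, and vice versa
  expect_true(all(ch$A1[bpD, lab == "serve_ND"] == 0))
  expect_true(all(ch$A1[bpND, lab == "serve_D"] == 0))
  expect_true(any(ch$A1[bpD, lab == "serve_D"] > 0))
  expect_true(any(ch$A1[bpND, lab == "serve_ND"] > 0))
  # no service progress during a busy period
  expect_true(all(ch$A2[bpD | bpND, ] == 0))
})

test_that("model selection guards unsupported configurations", {
  cfg_m2 <- workflow_config(prevalence = 0.1, se = 0.9, sp = 0.9, n_rad = 2,
                            read_time_diseased = 10,
                            read_time_nondiseased = 15, rho = 0.5)
  expect_error(compute_waits(cfg_m2), "single radiologist")
  cfg_m1 <- fig10_config(n_rad = 3)
  expect_error(compute_waits(cfg_m1), "n_rad")
  expect_error(compute_waits(fig10_config(rt_d = 10, rt_nd = 12),
                             model = "1"), "equal")
})
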