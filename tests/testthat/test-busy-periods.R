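test_that("M/M/1 busy-period moments match their closed forms", {
  m <- mm1_busy_period_moments(0.05, 0.2)
  expect_equal(unname(m), c(1 / 0.15, 2 / (0.04 * 0.75^3),
                            6 * 1.25 / (0.008 * 0.75^5)), tolerance = 1e-12)
  expect_equal(round(unname(m), 1), c(6.7, 118.5, 3950.6))
  # no competing arrivals: plain exponential service moments
  expect_equal(unname(mm1_busy_period_moments(0, 0.2)), c(5, 50, 750))
  expect_error(mm1_busy_period_moments(0.2, 0.2), "unstable")
  expect_error(mm1_busy_period_moments(0.3, 0.2), "unstable")
})

test_that("two-radiologist conditional busy periods are coherent and fit", {
  rates <- derive_rates(fig10_config(f = 0.2, n_rad = 2))
  bp <- busy_period_set_model1(rates)
  expect_setequal(bp$label, paste0("B", 1:6))
  # end probabilities per start state are exhaustive
  for (st in unique(bp$start_state)) {
    expect_equal(sum(bp$cond_prob[bp$start_state == st]), 1,
                 tolerance = 1e-10)
  }
  # each fitted phase type round-trips its conditional moments
  for (r in seq_len(nrow(bp))) {
    got <- unname(phase_type_moments(bp$fit[[r]]))
    want <- c(bp$m1[r], bp$m2[r], bp$m3[r])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("conditional busy periods agree with Monte-Carlo passage times", {
  rates <- derive_rates(fig10_config(f = 0.2, n_rad = 2))
  bp <- busy_period_set_model1(rates)
  set.seed(31)
  for (st in list(c(0, 2), c(1, 1), c(2, 0))) {
    mc <- mc_passage(rates$lambda_f, rates$mu_f, rates$lambda_pos,
                     rates$mu_pos, st, n_cycles = 8000)
    st_lab <- sprintf("(%d,%d)", st[1], st[2])
    rows <- bp[bp$start_state == st_lab, ]
    for (r in seq_len(nrow(rows))) {
      sel <- mc$end_state == rows$end_state[r]
      p_hat <- mean(sel)
      se_p <- sqrt(p_hat * (1 - p_hat) / length(sel))
      expect_lt(abs(p_hat - rows$cond_prob[r]), 3 * se_p + 1e-12)
      d <- mc$duration[sel]
      expect_lt(abs(mean(d) - rows$m1[r]), 3 * sd(d) / sqrt(length(d)))
      expect_lt(abs(mean(d^2) - rows$m2[r]), 3 * sd(d^2) / sqrt(length(d)))
    }
  }
})

test_that("single-radiologist busy periods reduce to known limits", {
  # equal read rates make the diseased and non-diseased AI-positive
  # initiations indistinguishable
  rates_eq <- derive_rates(fig10_config(f = 0.2))
  bp_eq <- busy_period_set_model2(rates_eq)
  b2 <- bp_eq[bp_eq$label == "B2", ]
  b3 <- bp_eq[bp_eq$label == "B3", ]
  expect_equal(c(b2$m1, b2$m2, b2$m3), c(b3$m1, b3$m2, b3$m3),
               tolerance = 1e-12)

  # with no AI-positive stream, B1 is the plain interrupting M/M/1 busy
  # period
  rates_f <- derive_rates(fig10_config(se = 0, sp = 1, f = 0.2))
  bp_f <- busy_period_set_model2(rates_f)
  b1 <- bp_f[bp_f$label == "B1", ]
  want <- mm1_busy_period_moments(rates_f$lambda_f, rates_f$mu_f)
  expect_equal(c(b1$m1, b1$m2, b1$m3), unname(want), tolerance = 1e-8)
  expect_true(all(bp_f$cond_prob == 1))
})

test_that("delay busy periods match Monte-Carlo workload clearing", {
  cfg <- workflow_config(prevalence = 0.2, se = 0.9, sp = 0.85, f = 0.25,
                         n_rad = 1, read_time_interrupting = 4,
                         read_time_diseased = 12, read_time_nondiseased = 7,
                         rho = 0.7)
  rates <- derive_rates(cfg)
  bp <- busy_period_set_model2(rates)
  lam <- rates$lambda_f + rates$lambda_pos
  w <- c(rates$lambda_f, rates$lambda_pos * rates$ppv,
         rates$lambda_pos * (1 - rates$ppv)) / lam
  svc_rates <- c(rates$mu_f, rates$mu_d, rates$mu_nd)
  rsvc <- function() rexp(1, sample(svc_rates, 1, prob = w))
  set.seed(17)
  for (r in seq_len(nrow(bp))) {
    mu0 <- svc_rates[match(bp$label[r], c("B1", "B2", "B3"))]
    d <- mc_delay_busy(6000, lam, function() rexp(1, mu0), rsvc)
    expect_lt(abs(mean(d) - bp$m1[r]), 3 * sd(d) / sqrt(length(d)))
    expect_lt(abs(mean(d^2) - bp$m2[r]), 3 * sd(d^2) / sqrt(length(d)))
  }
})
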