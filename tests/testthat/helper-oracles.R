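# Closed-form queueing oracles and small Monte-Carlo samplers used to
# verify the package's chain solutions independently.

fig10_config <- function(se = 0.95, sp = 0.89, rho = 0.8, f = 0,
                         n_rad = 1L, rt_d = 10, rt_nd = 10) {
  workflow_config(prevalence = 0.1, se = se, sp = sp, f = f, n_rad = n_rad,
                  read_time_interrupting = 5, read_time_diseased = rt_d,
                  read_time_nondiseased = rt_nd, rho = rho)
}

# M/M/1 mean queue wait
mm1_wq <- function(lambda, mu) lambda / (mu * (mu - lambda))

# M/M/c mean queue wait (Erlang C)
mmc_wq <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  p0 <- 1 / (sum(a^(0:(c - 1)) / factorial(0:(c - 1))) +
               a^c / (factorial(c) * (1 - rho)))
  pw <- a^c / (factorial(c) * (1 - rho)) * p0
  pw / (c * mu - lambda)
}

# M/G/1 Pollaczek-Khinchine mean queue wait from service moments
pk_wq <- function(lambda, s1, s2) lambda * s2 / (2 * (1 - lambda * s1))

# mean queue wait of class j in a preemptive-resume priority M/M/1 with
# exponential per-class services (classes ordered by priority)
preemptive_wq <- function(lambda, mu, j) {
  rho <- lambda / mu
  rho_h <- if (j > 1) sum(rho[seq_len(j - 1)]) else 0
  rho_hj <- rho_h + rho[j]
  (1 / mu[j]) * (1 / (1 - rho_h) - 1) +
    sum(lambda[seq_len(j)] / mu[seq_len(j)]^2) / ((1 - rho_h) * (1 - rho_hj))
}

# direct sampler for a fitted Erlang-Coxian distribution
sample_ec <- function(n, fit) {
  x <- rexp(n, fit$lambda_x1) +
    (runif(n) < fit$p_x) * rexp(n, fit$lambda_x2)
  if (fit$n_erlang > 0) {
    x <- x + rgamma(n, shape = fit$n_erlang, rate = fit$lambda_y)
  }
  x
}

# Monte-Carlo passage through the two-radiologist high-priority sub-chain:
# start at (n_f, n_p), run until n_f + n_p == 1, return end state and time.
mc_passage <- function(lf, mf, lp, mp, start, n_cycles) {
  end_state <- character(n_cycles)
  duration <- numeric(n_cycles)
  for (r in seq_len(n_cycles)) {
    i <- start[1]; j <- start[2]; t <- 0
    repeat {
      sf <- min(i, 2); sp <- min(j, 2 - sf)
      rates <- c(lf, lp, sf * mf, sp * mp)
      tot <- sum(rates)
      t <- t + rexp(1, tot)
      ev <- sample.int(4, 1, prob = rates)
      if (ev == 1) i <- i + 1
      else if (ev == 2) j <- j + 1
      else if (ev == 3) i <- i - 1
      else j <- j - 1
      if (i + j == 1) break
    }
    end_state[r] <- if (i == 0) "(0,1)" else "(1,0)"
    duration[r] <- t
  }
  list(end_state = end_state, duration = duration)
}

# Monte-Carlo M/G/1-type delay busy period: initial work s0 (sampled by
# rs0), arrivals at rate lambda each adding work sampled by rsvc.
mc_delay_busy <- function(n_cycles, lambda, rs0, rsvc) {
  out <- numeric(n_cycles)
  for (r in seq_len(n_cycles)) {
    end <- rs0()
    t <- if (lambda > 0) rexp(1, lambda) else Inf
    while (t < end) {
      end <- end + rsvc()
      t <- t + rexp(1, lambda)
    }
    out[r] <- end
  }
  out
}
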