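#' @title Paired two-world discrete-event simulation
#'
#' @description
#' Every simulated patient image is placed simultaneously into two
#' worlds: one where the reading queue runs without a CADt (interrupting
#' before non-interrupting, FIFO within class) and one where AI-positive
#' images are prioritized over AI-negative ones. The arrival stream and
#' every read duration are identical across worlds — only the queue
#' discipline differs — so the per-image wait difference isolates the
#' effect of the device (common random numbers). Service is
#' preemptive-resume: a higher-priority arrival immediately interrupts a
#' lower-priority read, whose remaining work is stored and later resumed,
#' never resampled.
#'
#' @name simulator
NULL

# one world: preemptive-resume priority queue with n_servers servers.
# jobs are served in (priority, arrival-index) order; at every event the
# min(n_servers, active) head jobs of that order hold the servers, which
# preempts the most-recently-arrived lowest-priority job automatically.
des_world <- function(arr, prio, dur, n_servers, n_classes) {
  n <- length(arr)
  rem <- dur
  done <- rep(NA_real_, n)
  census <- matrix(0L, n, n_classes)
  active <- integer(0)
  t <- 0
  i <- 1L
  repeat {
    n_act <- length(active)
    if (n_act) {
      srv <- active[seq_len(min(n_servers, n_act))]
      w <- which.min(rem[srv])
      tc <- t + rem[srv[w]]
      jc <- srv[w]
    } else {
      tc <- Inf
    }
    ta <- if (i <= n) arr[i] else Inf
    if (is.infinite(ta) && is.infinite(tc)) break
    if (ta <= tc) {
      if (n_act) rem[srv] <- rem[srv] - (ta - t)
      t <- ta
      if (n_act) census[i, ] <- tabulate(prio[active], n_classes)
      pos <- sum(prio[active] <= prio[i])
      active <- append(active, i, after = pos)
      i <- i + 1L
    } else {
      rem[srv] <- rem[srv] - (tc - t)
      t <- tc
      done[jc] <- t
      active <- active[active != jc]
    }
  }
  list(done = done, census = census)
}

#' Simulate one reading-queue run in both worlds
#'
#' Generates one Poisson arrival stream, assigns interrupting status,
#' disease status and the AI call by Bernoulli thinning, draws one
#' exponential read duration per image at its subgroup's rate, and plays
#' the identical stream through the without-CADt and with-CADt queues.
#'
#' Draws are taken from the current RNG state in a fixed order
#' (inter-arrival times, interrupting flags, disease flags, AI-call
#' uniforms, one standardized duration per image), so a run is fully
#' reproducible from a seed regardless of the realized class mix.
#'
#' @param cfg A `workflow_config`.
#' @param n_patients Number of images in the run (about 2000 in a
#'   full-size protocol).
#' @param seed Optional integer seed set before drawing.
#' @return A tibble with one row per image: `arrival_time`,
#'   `is_interrupting`, `is_diseased`, `ai_positive`, `read_duration`
#'   (minutes, shared across worlds), `wait_without`, `wait_with`
#'   (queue waits, minutes), and the pre-arrival class census in each
#'   world (`census_without_f`, `census_without_nonf`, `census_with_f`,
#'   `census_with_pos`, `census_with_neg`).
#' @export
simulate_run <- function(cfg, n_patients = 2000L, seed = NULL) {
  cfg <- validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  lambda <- config_lambda(cfg)
  n <- as.integer(n_patients)

  arrival <- cumsum(stats::rexp(n, lambda))
  is_f <- stats::runif(n) < cfg$f
  is_d <- !is_f & stats::runif(n) < cfg$prevalence
  u_ai <- stats::runif(n)
  ai_pos <- !is_f & ifelse(is_d, u_ai < cfg$se, u_ai < 1 - cfg$sp)
  rate <- ifelse(is_f, 1 / cfg$read_time_interrupting,
                 ifelse(is_d, 1 / cfg$read_time_diseased,
                        1 / cfg$read_time_nondiseased))
  dur <- stats::rexp(n, 1) / rate

  prio_without <- ifelse(is_f, 1L, 2L)
  prio_with <- ifelse(is_f, 1L, ifelse(ai_pos, 2L, 3L))

  wo <- des_world(arrival, prio_without, dur, cfg$n_rad, 2L)
  wi <- des_world(arrival, prio_with, dur, cfg$n_rad, 3L)

  tibble::tibble(
    arrival_time = arrival,
    is_interrupting = is_f,
    is_diseased = is_d,
    ai_positive = ai_pos,
    read_duration = dur,
    wait_without = wo$done - arrival - dur,
    wait_with = wi$done - arrival - dur,
    census_without_f = wo$census[, 1L],
    census_without_nonf = wo$census[, 2L],
    census_with_f = wi$census[, 1L],
    census_with_pos = wi$census[, 2L],
    census_with_neg = wi$census[, 3L]
  )
}

#' Run a batch of paired simulations
#'
#' Repeats [simulate_run()] `n_runs` times with per-run child seeds
#' derived from the root seed (`seed + run index`), aggregates the
#' diseased and non-diseased mean waits per run, and reports two 95%
#' intervals for each delta: the 2.5/97.5 percentiles of the per-run
#' means and the normal-theory interval of the grand mean.
#'
#' @param cfg A `workflow_config`.
#' @param n_runs Number of independent runs (protocol default 200).
#' @param patients_per_run Images per run (protocol default 2000).
#' @param seed Root integer seed; recorded in the result.
#' @param burn_in Images discarded from the start of each run before
#'   aggregating waits (default 0, mirroring the protocol; short runs
#'   started empty bias waits slightly low).
#' @return An object of class `cadt_sim` with elements `per_run` (tibble
#'   of per-run means), `summary` (one-row tibble with means, deltas and
#'   both interval types), and the call parameters.
#' @examples
#' cfg <- workflow_config(prevalence = 0.1, se = 0.95, sp = 0.89, rho = 0.5)
#' sim <- run_batch(cfg, n_runs = 10, patients_per_run = 200, seed = 1)
#' glance(sim)
#' @export
run_batch <- function(cfg, n_runs = 200L, patients_per_run = 2000L,
                      seed = 1L, burn_in = 0L) {
  cfg <- validate_config(cfg)
  stopifnot(n_runs >= 1, patients_per_run > burn_in)
  per_run <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rec <- simulate_run(cfg, patients_per_run, seed = seed + r)
    if (burn_in > 0) rec <- rec[-seq_len(burn_in), , drop = FALSE]
    nonf <- !rec$is_interrupting
    d <- rec$is_diseased
    per_run[[r]] <- tibble::tibble(
      run = r,
      w_d_without = mean(rec$wait_without[d]),
      w_d_with = mean(rec$wait_with[d]),
      w_nd_without = mean(rec$wait_without[nonf & !d]),
      w_nd_with = mean(rec$wait_with[nonf & !d]),
      w_pos = mean(rec$wait_with[rec$ai_positive]),
      w_neg = mean(rec$wait_with[nonf & !rec$ai_positive]),
      n_diseased = sum(d)
    )
  }
  per_run <- dplyr::bind_rows(per_run)
  per_run$delta_w_d <- per_run$w_d_with - per_run$w_d_without
  per_run$delta_w_nd <- per_run$w_nd_with - per_run$w_nd_without

  ci <- function(x) {
    x <- x[is.finite(x)]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    se <- stats::sd(x) / sqrt(length(x))
    c(lo_pct = q[1], hi_pct = q[2],
      lo_norm = mean(x) - 1.96 * se, hi_norm = mean(x) + 1.96 * se)
  }
  cd <- ci(per_run$delta_w_d)
  cn <- ci(per_run$delta_w_nd)
  summary <- tibble::tibble(
    w_d_without = mean(per_run$w_d_without, na.rm = TRUE),
    w_d_with = mean(per_run$w_d_with, na.rm = TRUE),
    delta_w_d = mean(per_run$delta_w_d, na.rm = TRUE),
    delta_w_d_lo = cd[["lo_pct"]], delta_w_d_hi = cd[["hi_pct"]],
    delta_w_d_lo_norm = cd[["lo_norm"]], delta_w_d_hi_norm = cd[["hi_norm"]],
    w_nd_without = mean(per_run$w_nd_without, na.rm = TRUE),
    w_nd_with = mean(per_run$w_nd_with, na.rm = TRUE),
    delta_w_nd = mean(per_run$delta_w_nd, na.rm = TRUE),
    delta_w_nd_lo = cn[["lo_pct"]], delta_w_nd_hi = cn[["hi_pct"]]
  )
  structure(
    list(per_run = per_run, summary = summary, config = cfg,
         n_runs = n_runs, patients_per_run = patients_per_run,
         seed = seed, burn_in = burn_in),
    class = "cadt_sim"
  )
}

#' @export
print.cadt_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cadt_sim> %d runs x %d patients (seed %d)\n", x$n_runs,
              x$patients_per_run, x$seed))
  cat(sprintf("  delta W_D = %.2f min  [95%% run-percentile %.2f, %.2f]\n",
              s$delta_w_d, s$delta_w_d_lo, s$delta_w_d_hi))
  cat(sprintf("  delta W_ND = %.2f min [95%% run-percentile %.2f, %.2f]\n",
              s$delta_w_nd, s$delta_w_nd_lo, s$delta_w_nd_hi))
  invisible(x)
}

#' Tidy a simulation batch
#'
#' @param x A `cadt_sim`.
#' @param ... Unused.
#' @return The per-run tibble of mean waits and deltas.
#' @method tidy cadt_sim
#' @export
tidy.cadt_sim <- function(x, ...) x$per_run

#' @method glance cadt_sim
#' @export
glance.cadt_sim <- function(x, ...) x$summary

#' Empirical pre-arrival state distribution
#'
#' Tallies the class census recorded just before each arrival. Poisson
#' arrivals see time averages, so these empirical frequencies estimate
#' the stationary state probabilities of the queueing chain and are
#' directly comparable with [solve_qbd()] output.
#'
#' @param records A tibble of patient records from [simulate_run()] (or
#'   several concatenated).
#' @param column Which census column to tally (e.g.
#'   `"census_without_nonf"`).
#' @return A tibble with `n_in_system` and `probability`, summing to 1.
#' @export
state_census_distribution <- function(records,
                                      column = "census_without_nonf") {
  x <- records[[column]]
  if (length(x) < 1) stop("no records supplied", call. = FALSE)
  tab <- table(factor(x, levels = 0:max(x)))
  tibble::tibble(
    n_in_system = as.integer(names(tab)),
    probability = as.numeric(tab) / length(x)
  )
}
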