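#' @title Busy periods of the higher-priority work
#'
#' @description
#' A busy period is the interval during which every radiologist is
#' occupied by work of higher priority than the tagged class, so the
#' tagged class cannot begin (or resume) service. Recursive
#' dimensionality reduction replaces each busy period by a phase-type
#' distribution matched to its first three moments; with several possible
#' end states the moments are computed conditionally on the end state,
#' together with the conditional end probabilities.
#'
#' Single-server busy periods have Takacs-type closed forms; the
#' two-radiologist case is a first-passage problem on the
#' (interrupting, AI-positive) sub-chain, solved here by linear systems on
#' a truncated generator.
#'
#' @name busy_periods
NULL

exp_moments <- function(mu) c(1 / mu, 2 / mu^2, 6 / mu^3)

mixture_moments <- function(weights, moment_list) {
  w <- weights / sum(weights)
  out <- numeric(3)
  for (i in seq_along(w)) out <- out + w[i] * moment_list[[i]]
  out
}

#' Closed-form moments of an M/M/1 busy period
#'
#' With arrival rate \eqn{\lambda}, service rate \eqn{\mu} and
#' \eqn{\rho = \lambda/\mu < 1}:
#' \deqn{m_1 = \frac{1}{\mu(1-\rho)}, \quad
#'       m_2 = \frac{2}{\mu^2 (1-\rho)^3}, \quad
#'       m_3 = \frac{6 (1+\rho)}{\mu^3 (1-\rho)^5}.}
#' At \eqn{\lambda = 0} these reduce to the exponential moments
#' \eqn{k!/\mu^k}.
#'
#' @param lambda Arrival rate (per minute), `>= 0`.
#' @param mu Service rate (per minute), `> lambda`.
#' @return Named numeric vector `c(m1, m2, m3)` in minutes^k.
#' @examples
#' mm1_busy_period_moments(0.05, 0.2)
#' @export
mm1_busy_period_moments <- function(lambda, mu) {
  if (lambda >= mu) {
    stop("unstable busy period: lambda >= mu", call. = FALSE)
  }
  rho <- lambda / mu
  out <- c(
    m1 = 1 / (mu * (1 - rho)),
    m2 = 2 / (mu^2 * (1 - rho)^3),
    m3 = 6 * (1 + rho) / (mu^3 * (1 - rho)^5)
  )
  out
}

# Takacs moments of the ordinary M/G/1 busy period with service moments s.
mg1_busy_period_moments <- function(lambda, s) {
  rho <- lambda * s[1]
  if (rho >= 1) stop("unstable busy period: rho >= 1", call. = FALSE)
  c(
    m1 = s[1] / (1 - rho),
    m2 = s[2] / (1 - rho)^3,
    m3 = s[3] / (1 - rho)^4 + 3 * lambda * s[2]^2 / (1 - rho)^5
  )
}

# Moments of the delay busy period initiated by a job with service moments
# s0 while arrivals at rate lambda bring generic services with moments s:
# T = S0 evaluated at theta(s) = s + lambda (1 - B*(s)).
mg1_delay_busy_moments <- function(lambda, s, s0) {
  if (lambda == 0) return(s0)
  b <- mg1_busy_period_moments(lambda, s)
  rho <- lambda * s[1]
  c(
    m1 = s0[1] / (1 - rho),
    m2 = s0[2] / (1 - rho)^2 + s0[1] * lambda * b[2],
    m3 = s0[3] / (1 - rho)^3 + 3 * s0[2] * lambda * b[2] / (1 - rho) +
      s0[1] * lambda * b[3]
  )
}

new_busy_spec <- function(label, start_state, end_state, cond_prob, moments) {
  tibble::tibble(
    label = label, start_state = start_state, end_state = end_state,
    cond_prob = cond_prob,
    m1 = unname(moments[1]), m2 = unname(moments[2]), m3 = unname(moments[3]),
    fit = list(fit_ec(unname(moments)))
  )
}

# Truncation depth for the first-passage sub-chain: deep enough that the
# geometric decay of excursions leaves mass < ~1e-13 beyond the cut.
passage_truncation <- function(decay) {
  decay <- min(max(decay, 0.05), 0.97)
  min(max(ceiling(log(1e-13) / log(decay)), 30L), 400L)
}

#' Conditional busy periods for two radiologists (equal-rate model)
#'
#' With two radiologists and a CADt, the AI-negative class is blocked
#' whenever interrupting plus AI-positive images occupy both radiologists
#' (\eqn{n_f + n_+ \ge 2}). A busy period starts from (0,2), (1,1) or
#' (2,0) and ends at (0,1) or (1,0), giving six conditional busy periods
#' B1-B6. Their end probabilities and conditional first three moments are
#' obtained from first-passage linear systems on the truncated
#' high-priority sub-chain, then each is fitted to an Erlang-Coxian
#' distribution ([fit_ec()]; the region test decides whether an Erlang
#' stage is needed).
#'
#' Busy periods with conditional probability below `1e-12` are dropped and
#' their mass redistributed to the sibling end state, so degenerate
#' moment sets are never fitted.
#'
#' @param rates A one-row tibble from [derive_rates()] (needs `lambda_f`,
#'   `mu_f`, `lambda_pos`, `mu_pos`).
#' @param n_rad Radiologist count; only 2 is supported analytically.
#' @return A tibble with one row per retained busy period: `label`,
#'   `start_state`, `end_state`, `cond_prob`, `m1`-`m3` (minutes^k), and
#'   a `fit` list-column of `ec_fit` objects.
#' @export
busy_period_set_model1 <- function(rates, n_rad = 2L) {
  if (n_rad != 2L) {
    stop("conditional busy-period sets are implemented for n_rad = 2 only",
         call. = FALSE)
  }
  lf <- rates$lambda_f; mf <- rates$mu_f
  lp <- rates$lambda_pos; mp <- rates$mu_pos
  util <- (lf / mf + lp / mp) / 2
  if (util >= 1 - 1e-9) {
    stop("unstable high-priority aggregate: utilization ", format(util),
         call. = FALSE)
  }
  K <- passage_truncation(max(lf / (2 * mf), lp / (2 * mp)))

  # transient states: n_f + n_+ >= 2, n_f <= K, n_+ <= K
  grid <- expand.grid(i = 0:K, j = 0:K)
  grid <- grid[grid$i + grid$j >= 2L, , drop = FALSE]
  idx <- matrix(NA_integer_, K + 1L, K + 1L)
  idx[cbind(grid$i + 1L, grid$j + 1L)] <- seq_len(nrow(grid))
  n <- nrow(grid)

  i <- grid$i; j <- grid$j
  sf <- pmin(i, 2L)                  # radiologists on interrupting work
  sp <- pmin(j, 2L - sf)             # the rest on AI-positive work
  s_all <- seq_len(n)
  diag_out <- numeric(n)
  r01 <- numeric(n); r10 <- numeric(n)
  rows <- list(); cols <- list(); vals <- list()
  put <- function(from, to_i, to_j, rate) {
    # transient-to-transient transitions; arrivals beyond the truncation
    # boundary were filtered out by the caller
    rows[[length(rows) + 1L]] <<- from
    cols[[length(cols) + 1L]] <<- idx[cbind(to_i + 1L, to_j + 1L)]
    vals[[length(vals) + 1L]] <<- rate
    diag_out[from] <<- diag_out[from] + rate
  }
  # interrupting arrivals
  k <- which(i < K & lf > 0)
  if (length(k)) put(s_all[k], i[k] + 1L, j[k], rep(lf, length(k)))
  # AI-positive arrivals
  k <- which(j < K & lp > 0)
  if (length(k)) put(s_all[k], i[k], j[k] + 1L, rep(lp, length(k)))
  # interrupting departures
  k <- which(sf > 0)
  abs_k <- k[i[k] - 1L + j[k] == 1L]
  trn_k <- setdiff(k, abs_k)
  if (length(trn_k)) put(s_all[trn_k], i[trn_k] - 1L, j[trn_k],
                         sf[trn_k] * mf)
  for (s0 in abs_k) {
    rate <- sf[s0] * mf
    if (i[s0] - 1L == 0L) r01[s0] <- r01[s0] + rate else r10[s0] <- r10[s0] + rate
    diag_out[s0] <- diag_out[s0] + rate
  }
  # AI-positive departures
  k <- which(sp > 0)
  abs_k <- k[i[k] + j[k] - 1L == 1L]
  trn_k <- setdiff(k, abs_k)
  if (length(trn_k)) put(s_all[trn_k], i[trn_k], j[trn_k] - 1L,
                         sp[trn_k] * mp)
  for (s0 in abs_k) {
    rate <- sp[s0] * mp
    if (i[s0] == 0L) r01[s0] <- r01[s0] + rate else r10[s0] <- r10[s0] + rate
    diag_out[s0] <- diag_out[s0] + rate
  }
  U <- Matrix::sparseMatrix(i = c(unlist(rows), s_all),
                            j = c(unlist(cols), s_all),
                            x = c(unlist(vals), -diag_out), dims = c(n, n))
  negU <- -U
  h <- list(`(0,1)` = Matrix::solve(negU, r01),
            `(1,0)` = Matrix::solve(negU, r10))
  mom <- lapply(h, function(hv) {
    g1 <- Matrix::solve(negU, hv)
    g2 <- Matrix::solve(negU, g1)
    g3 <- Matrix::solve(negU, g2)
    list(m1 = as.numeric(g1), m2 = 2 * as.numeric(g2), m3 = 6 * as.numeric(g3))
  })

  starts <- list(`(0,2)` = idx[1L, 3L], `(1,1)` = idx[2L, 2L],
                 `(2,0)` = idx[3L, 1L])
  labels <- matrix(c("B1", "B2", "B3", "B4", "B5", "B6"), nrow = 2L)

  out <- list()
  for (si in seq_along(starts)) {
    s0 <- starts[[si]]
    probs <- c(as.numeric(h[["(0,1)"]][s0]), as.numeric(h[["(1,0)"]][s0]))
    keep <- probs >= 1e-12
    probs <- probs / sum(probs[keep])  # redistribute dropped mass
    for (ei in 1:2) {
      if (!keep[ei]) next
      end <- names(h)[ei]
      mk <- mom[[ei]]
      p_raw <- c(h[["(0,1)"]][s0], h[["(1,0)"]][s0])[ei]
      m <- c(mk$m1[s0], mk$m2[s0], mk$m3[s0]) / as.numeric(p_raw)
      out[[length(out) + 1L]] <- new_busy_spec(
        labels[ei, si], names(starts)[si], end, probs[ei], m
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Busy periods for the single-radiologist unequal-rate model
#'
#' With one radiologist, an AI-negative image is blocked whenever any
#' interrupting or AI-positive work is present. Three busy periods are
#' distinguished by the job in service at onset: B1 starts with an
#' interrupting read, B2 with a diseased (true-positive) AI-positive read,
#' and B3 with a non-diseased (false-positive) AI-positive read. Each is
#' the M/G/1 delay busy period of the aggregated high-priority stream
#' (rate \eqn{\lambda_f + \lambda_+}, hyperexponential services) initiated
#' by the respective exponential read, with closed-form moments; every end
#' probability is 1 because the period always returns to the same resumed
#' AI-negative image.
#'
#' @param rates A one-row tibble from [derive_rates()].
#' @return A tibble in the same shape as [busy_period_set_model1()].
#' @export
busy_period_set_model2 <- function(rates) {
  lf <- rates$lambda_f; lp <- rates$lambda_pos
  lam <- lf + lp
  weights <- c(lf, lp * rates$ppv, lp * (1 - rates$ppv))
  svc <- list(exp_moments(rates$mu_f), exp_moments(rates$mu_d),
              exp_moments(rates$mu_nd))
  if (lam > 0) {
    s <- mixture_moments(weights, svc)
    if (lam * s[1] >= 1 - 1e-9) {
      stop("unstable high-priority aggregate: utilization ",
           format(lam * s[1]), call. = FALSE)
    }
  }
  specs <- list()
  init <- list(
    list(label = "B1", start = "(1+, 0+, n-)", s0 = svc[[1]], active = lf > 0),
    list(label = "B2", start = "(0+, 1+, D, n-)", s0 = svc[[2]],
         active = weights[2] > 0),
    list(label = "B3", start = "(0+, 1+, ND, n-)", s0 = svc[[3]],
         active = weights[3] > 0)
  )
  for (b in init) {
    if (!b$active) next
    m <- mg1_delay_busy_moments(lam, s, b$s0)
    specs[[length(specs) + 1L]] <-
      new_busy_spec(b$label, b$start, "(0, 0, n-, j)", 1, m)
  }
  dplyr::bind_rows(specs)
}
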