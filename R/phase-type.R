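#' @title Erlang-Coxian phase-type matching of three moments
#'
#' @description
#' The priority-queue chains replace every busy period (an interval during
#' which no radiologist is free for the tagged class) with a small
#' phase-type distribution matched to the busy period's first three raw
#' moments. The family used is the Erlang-Coxian (EC) distribution: a
#' chain of identical-rate Erlang phases feeding a two-phase Coxian. Most
#' busy periods are at least as variable as an exponential and need only
#' the two Coxian phases; low-variability (hypoexponential) moment triples
#' additionally need Erlang phases, decided at run time by a
#' representability test.
#'
#' @name phase_type
NULL

# quadratic solve for the two-phase Coxian: phase 1 rate 1/u, phase 2 rate
# 1/w entered with probability p.  Works on m1-normalized moments; returns
# NULL when the triple is not Coxian-2-representable.
coxian2_solve <- function(m) {
  m1 <- m[[1]]; m2 <- m[[2]]; m3 <- m[[3]]
  n2 <- m2 / m1^2
  n3 <- m3 / m1^3
  A <- 1 - n2 / 2
  B <- n3 / 6 - n2 / 2
  C <- n2^2 / 4 - n3 / 6

  finish <- function(u) {
    if (!is.finite(u) || u <= 0 || u > 1 + 1e-12) return(NULL)
    u <- min(u, 1)
    s <- 1 - u
    if (s < 1e-12) {
      # all mass in the first phase: exponential
      return(list(u = m1, w = m1, p = 0))
    }
    w <- (n2 / 2 - u) / s
    if (!is.finite(w) || w <= 0) return(NULL)
    p <- s / w
    if (p < -1e-12 || p > 1 + 1e-12) return(NULL)
    p <- min(max(p, 0), 1)
    list(u = u * m1, w = w * m1, p = p)
  }

  eps <- 1e-12
  if (abs(A) < eps) {
    if (abs(B) < eps) {
      # exponential-like: consistent only when C vanishes too
      if (abs(C) < 1e-9) return(list(u = m1, w = m1, p = 0))
      return(NULL)
    }
    return(finish(-C / B))
  }
  disc <- B^2 - 4 * A * C
  scale <- max(B^2, abs(4 * A * C), eps)
  if (disc < -1e-9 * scale) return(NULL)
  disc <- max(disc, 0)
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  for (u in roots) {
    out <- finish(u)
    if (!is.null(out)) return(out)
  }
  NULL
}

check_moments <- function(m) {
  if (length(m) != 3L || any(!is.finite(m))) {
    stop("moments must be three finite numbers (m1, m2, m3)", call. = FALSE)
  }
  if (m[[1]] <= 0) stop("infeasible moments: m1 must be > 0", call. = FALSE)
  if (m[[2]] < m[[1]]^2 * (1 - 1e-12)) {
    stop("infeasible moments: m2 < m1^2 implies negative variance",
         call. = FALSE)
  }
  if (m[[3]] <= 0 || m[[1]] * m[[3]] < m[[2]]^2 * (1 - 1e-12)) {
    stop("infeasible moments: m1*m3 < m2^2 violates the nonnegative-",
         "distribution bound", call. = FALSE)
  }
  as.numeric(m)
}

#' Does a moment triple need Erlang phases?
#'
#' Returns `TRUE` when the triple `(m1, m2, m3)` lies outside the region
#' representable by a two-phase Coxian distribution (squared coefficient of
#' variation below 1/2, or a normalized third moment outside the Coxian-2
#' band), so the EC fit must prepend Erlang phases. Boundary cases such as
#' the Erlang-2 moments are still Coxian-2-representable and return
#' `FALSE`.
#'
#' @param m Numeric vector of the first three raw moments (minutes,
#'   minutes^2, minutes^3).
#' @return Logical scalar.
#' @examples
#' needs_erlang_stage(c(10, 200, 6000))  # exponential: FALSE
#' needs_erlang_stage(c(10, 125, 1875))  # Erlang-4: TRUE
#' @export
needs_erlang_stage <- function(m) {
  m <- check_moments(m)
  is.null(coxian2_solve(m))
}

new_ec_fit <- function(p_x, lambda_x1, lambda_x2, n_erlang = 0L,
                       lambda_y = 0, moments) {
  structure(
    list(
      p_ec = 1, n_ec = as.integer(n_erlang + 2L), n_erlang = as.integer(n_erlang),
      lambda_y = lambda_y, p_x = p_x,
      lambda_x1 = lambda_x1, lambda_x2 = lambda_x2,
      t0 = 0, t01 = lambda_y,
      t1 = (1 - p_x) * lambda_x1, t12 = p_x * lambda_x1, t2 = lambda_x2,
      moments = moments
    ),
    class = "ec_fit"
  )
}

#' Fit a two-phase Coxian to three moments
#'
#' Closed-form fit of the simplified EC distribution (no Erlang phases:
#' `p_ec = 1`, `n_ec = 2`, `lambda_y = 0`). The first Coxian phase has
#' rate `lambda_x1`; with probability `p_x` the second phase (rate
#' `lambda_x2`) is visited before absorption. The exponential transition
#' rates used when embedding the fit into a Markov chain are
#' `t1 = (1 - p_x) lambda_x1`, `t12 = p_x lambda_x1`, `t2 = lambda_x2`.
#'
#' @inheritParams needs_erlang_stage
#' @return An object of class `ec_fit`; see [tidy.ec_fit()].
#' @examples
#' fit <- fit_coxian2(c(10, 300, 15000))
#' phase_type_moments(fit)
#' @export
fit_coxian2 <- function(m) {
  m <- check_moments(m)
  sol <- coxian2_solve(m)
  if (is.null(sol)) {
    stop("moments are not two-phase-Coxian representable; use fit_ec()",
         call. = FALSE)
  }
  new_ec_fit(p_x = sol$p, lambda_x1 = 1 / sol$u, lambda_x2 = 1 / sol$w,
             moments = m)
}

#' Fit an Erlang-Coxian distribution to three moments
#'
#' Delegates to [fit_coxian2()] whenever the triple is representable
#' without Erlang phases. Otherwise the smallest Erlang stage count `k` is
#' found such that, after deconvolving an Erlang-`k` with a suitable rate
#' `lambda_y`, the residual moments admit a valid Coxian-2 fit; the Erlang
#' rate is picked deterministically from the middle of the feasible
#' interval. Because the convolution moment identities are exact, any
#' feasible choice round-trips the target moments to machine precision.
#'
#' @inheritParams needs_erlang_stage
#' @param max_erlang Largest Erlang stage count tried before declaring the
#'   triple infeasible.
#' @return An object of class `ec_fit`.
#' @examples
#' fit <- fit_ec(c(10, 125, 1875))  # Erlang-4 moments
#' fit$n_erlang
#' phase_type_moments(fit)
#' @export
fit_ec <- function(m, max_erlang = 60L) {
  m <- check_moments(m)
  sol <- coxian2_solve(m)
  if (!is.null(sol)) {
    return(new_ec_fit(p_x = sol$p, lambda_x1 = 1 / sol$u,
                      lambda_x2 = 1 / sol$w, moments = m))
  }
  # exact Erlang-n targets sit on the boundary of the k = n - 2 region, a
  # single point a grid search can miss; recognize them directly
  scv <- m[2] / m[1]^2 - 1
  if (scv > 0) {
    n <- round(1 / scv)
    if (n >= 3) {
      lam <- n / m[1]
      m_erl <- c(n / lam, n * (n + 1) / lam^2, n * (n + 1) * (n + 2) / lam^3)
      if (max(abs(m_erl - m) / m) < 1e-9) {
        return(new_ec_fit(p_x = 1, lambda_x1 = lam, lambda_x2 = lam,
                          n_erlang = n - 2L, lambda_y = lam, moments = m))
      }
    }
  }
  alphas <- seq(0.01, 0.99, by = 0.005)
  for (k in seq_len(max_erlang)) {
    feas <- vector("list", length(alphas))
    for (i in seq_along(alphas)) {
      e1 <- alphas[i] * m[1]
      lam_y <- k / e1
      e2 <- k * (k + 1) / lam_y^2
      e3 <- k * (k + 1) * (k + 2) / lam_y^3
      c1 <- m[1] - e1
      c2 <- m[2] - e2 - 2 * e1 * c1
      c3 <- m[3] - e3 - 3 * e2 * c1 - 3 * e1 * c2
      if (c1 <= 0 || c2 <= c1^2 || c3 <= 0) next
      feas[[i]] <- coxian2_solve(c(c1, c2, c3))
    }
    ok <- which(!vapply(feas, is.null, logical(1)))
    if (length(ok) > 0) {
      pick <- ok[ceiling(length(ok) / 2)]
      sol <- feas[[pick]]
      return(new_ec_fit(p_x = sol$p, lambda_x1 = 1 / sol$u,
                        lambda_x2 = 1 / sol$w, n_erlang = k,
                        lambda_y = k / (alphas[pick] * m[1]), moments = m))
    }
  }
  stop("infeasible moments: no Erlang-Coxian fit found with up to ",
       max_erlang, " Erlang phases", call. = FALSE)
}

# transient generator S and entry row for an ec_fit; absorption rates are
# -rowSums(S).  Phase order: Erlang 1..k, Coxian X1, Coxian X2.
ec_transient_generator <- function(fit) {
  k <- fit$n_erlang
  n <- k + 2L
  S <- matrix(0, n, n)
  if (k > 0) {
    for (i in seq_len(k)) {
      S[i, i] <- -fit$lambda_y
      S[i, i + 1L] <- fit$lambda_y
    }
  }
  x1 <- k + 1L
  x2 <- k + 2L
  S[x1, x1] <- -fit$lambda_x1
  S[x1, x2] <- fit$t12
  S[x2, x2] <- -fit$lambda_x2
  alpha <- numeric(n)
  alpha[1L] <- 1
  list(S = S, alpha = alpha, absorb = -rowSums(S))
}

#' Exact moments of a fitted phase-type distribution
#'
#' Closed-form absorption-time moments \eqn{m_k = k!\,\alpha (-S)^{-k}
#' \mathbf{1}} of the phase-type distribution described by an `ec_fit`.
#' Serves as the oracle against which every fit is verified to round-trip.
#'
#' @param fit An `ec_fit` from [fit_coxian2()] or [fit_ec()].
#' @return Named numeric vector `c(m1, m2, m3)`.
#' @export
phase_type_moments <- function(fit) {
  stopifnot(inherits(fit, "ec_fit"))
  g <- ec_transient_generator(fit)
  x <- rep(1, nrow(g$S))
  out <- numeric(3)
  for (k in 1:3) {
    x <- solve(-g$S, x)
    out[k] <- factorial(k) * sum(g$alpha * x)
  }
  names(out) <- c("m1", "m2", "m3")
  out
}

#' @export
print.ec_fit <- function(x, ...) {
  cat(sprintf("<ec_fit> %d phase(s): %d Erlang + Coxian-2\n", x$n_ec,
              x$n_erlang))
  cat(sprintf("  lambda_y: %.6g  p_x: %.6g  lambda_x1: %.6g  lambda_x2: %.6g\n",
              x$lambda_y, x$p_x, x$lambda_x1, x$lambda_x2))
  mom <- phase_type_moments(x)
  cat(sprintf("  moments: %.6g  %.6g  %.6g\n", mom[1], mom[2], mom[3]))
  invisible(x)
}

#' Tidy an Erlang-Coxian fit
#'
#' @param x An `ec_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`),
#'   covering the branch probabilities, phase rates and the derived `t`
#'   transition rates.
#' @method tidy ec_fit
#' @export
tidy.ec_fit <- function(x, ...) {
  terms <- c("p_ec", "n_ec", "n_erlang", "lambda_y", "p_x", "lambda_x1",
             "lambda_x2", "t0", "t01", "t1", "t12", "t2")
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(t) as.numeric(x[[t]]), numeric(1))
  )
}

#' @method glance ec_fit
#' @export
glance.ec_fit <- function(x, ...) {
  mom <- phase_type_moments(x)
  tibble::tibble(
    n_phases = x$n_ec, n_erlang = x$n_erlang,
    m1 = mom[[1]], m2 = mom[[2]], m3 = mom[[3]],
    max_rel_err = max(abs(mom - x$moments) / abs(x$moments))
  )
}
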