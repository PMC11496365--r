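#' @title Level-structured Markov chains and the matrix-geometric method
#'
#' @description
#' Every workflow model in the package reduces, after recursive
#' dimensionality reduction, to a quasi-birth-death (QBD) process: a
#' continuous-time Markov chain whose levels count the images of the
#' tagged priority class and whose within-level phases encode the state of
#' the higher-priority work (free server, interrupting count, busy-period
#' phases, disease status in service). The chain is solved exactly by the
#' matrix-geometric method: the rate matrix `R` satisfies
#' \eqn{A_0 + R A_1 + R^2 A_2 = 0}, the stationary tail is geometric,
#' \eqn{\pi_{b+k} = \pi_b R^k}, and mean queue lengths follow in closed
#' form from \eqn{(I-R)^{-1}} powers without truncation.
#'
#' @name qbd
NULL

#' Construct a quasi-birth-death chain
#'
#' A QBD chain is described by explicit boundary levels `0 .. b-1` (each
#' with its own `local`, `up`, and, from level 1, `down` block, allowing
#' level-dependent service rates and a differently sized level 0) and a
#' repeating portion from level `b` on with blocks `A0` (up), `A1`
#' (local), `A2` (down). `first_down` is the down-block from level `b`
#' into level `b-1`; it may differ from `A2` in shape when the last
#' boundary level has a different phase space.
#'
#' @param boundary List of boundary levels; each element is a list with
#'   matrices `local`, `up`, and (except level 0) `down`.
#' @param A0,A1,A2 Repeating up / local / down blocks (square, `m x m`).
#' @param first_down Down-block from the first repeating level into the
#'   last boundary level; defaults to `A2`.
#' @param phase_labels Optional character labels for the repeating phases.
#' @param class_rates Named numeric vector `c(lambda = , mu = )` of the
#'   tagged class, carried along for wait extraction.
#' @param level_meaning Free-text note naming the class the levels count.
#' @return An object of class `qbd_chain`.
#' @seealso [solve_qbd()], [solve_r_matrix()]
#' @export
qbd_chain <- function(boundary, A0, A1, A2, first_down = A2,
                      phase_labels = NULL,
                      class_rates = c(lambda = NA_real_, mu = NA_real_),
                      level_meaning = "tagged-class count") {
  m <- nrow(A1)
  stopifnot(is.matrix(A0), is.matrix(A1), is.matrix(A2),
            all(dim(A0) == m), all(dim(A2) == m), length(boundary) >= 1L)
  chk_rows <- function(M, what) {
    offdiag <- M - diag(diag(M), nrow(M))
    if (any(offdiag < -1e-12)) {
      stop("negative off-diagonal rate in ", what, call. = FALSE)
    }
  }
  chk_rows(A0, "A0"); chk_rows(A1, "A1"); chk_rows(A2, "A2")
  rs <- rowSums(A0 + A1 + A2)
  if (any(abs(rs) > 1e-10)) {
    stop("repeating generator rows do not sum to 0 (max |sum| = ",
         format(max(abs(rs))), ")", call. = FALSE)
  }
  b <- length(boundary)
  for (l in seq_len(b)) {
    lev <- boundary[[l]]
    rs <- rowSums(lev$local) + rowSums(lev$up)
    if (l > 1L) rs <- rs + rowSums(lev$down)
    if (any(abs(rs) > 1e-10)) {
      stop("boundary level ", l - 1L, " rows do not sum to 0", call. = FALSE)
    }
  }
  rs_b <- rowSums(A0) + rowSums(A1) + rowSums(first_down)
  if (any(abs(rs_b) > 1e-10)) {
    stop("first repeating level rows do not sum to 0", call. = FALSE)
  }
  structure(
    list(boundary = boundary, A0 = A0, A1 = A1, A2 = A2,
         first_down = first_down, phase_labels = phase_labels,
         class_rates = class_rates, level_meaning = level_meaning),
    class = "qbd_chain"
  )
}

#' @export
print.qbd_chain <- function(x, ...) {
  cat(sprintf("<qbd_chain> %d boundary level(s), %d repeating phase(s); levels count %s\n",
              length(x$boundary), nrow(x$A1), x$level_meaning))
  invisible(x)
}

spectral_radius <- function(M) {
  if (length(M) == 1L) return(abs(M[1L]))
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Solve the matrix-geometric rate matrix R
#'
#' Successive substitution \eqn{R \leftarrow -(A_0 + R^2 A_2) A_1^{-1}}
#' from `R = 0`, which converges monotonically to the minimal nonnegative
#' solution of \eqn{A_0 + R A_1 + R^2 A_2 = 0}. A drift pre-check on the
#' phase-marginal generator rejects unstable chains before iterating.
#'
#' @param chain A `qbd_chain`, or a list with elements `A0`, `A1`, `A2`.
#' @param tol Convergence tolerance on successive iterates (default
#'   `1e-12`).
#' @param max_iter Iteration cap.
#' @return The matrix `R`, with attributes `iterations` and `residual`
#'   (sup-norm of the quadratic identity).
#' @export
solve_r_matrix <- function(chain, tol = 1e-12, max_iter = 1e6) {
  A0 <- chain$A0; A1 <- chain$A1; A2 <- chain$A2
  m <- nrow(A1)

  # drift condition: theta A0 1 < theta A2 1 for the stationary phase mix
  A <- A0 + A1 + A2
  theta <- tryCatch({
    th <- qr.solve(rbind(t(A), rep(1, m)), c(rep(0, m), 1))
    pmax(th, 0) / sum(pmax(th, 0))
  }, error = function(e) NULL)
  if (!is.null(theta)) {
    up <- sum(theta * rowSums(A0))
    down <- sum(theta * rowSums(A2))
    if (up >= down * (1 - 1e-9)) {
      stop("unstable chain: mean upward drift ", format(up),
           " is not below mean downward drift ", format(down), call. = FALSE)
    }
  }

  A1inv <- solve(A1)
  R <- matrix(0, m, m)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Rn <- -(A0 + R %*% R %*% A2) %*% A1inv
    delta <- max(abs(Rn - R))
    R <- Rn
    if (delta < tol) break
    if (iter >= max_iter) {
      stop("R iteration did not converge within ", max_iter, " iterations",
           call. = FALSE)
    }
  }
  sr <- spectral_radius(R)
  if (sr >= 1 - 1e-9) {
    stop("unstable chain: spectral radius of R is ", format(sr), call. = FALSE)
  }
  resid <- max(abs(A0 + R %*% A1 + R %*% R %*% A2))
  structure(R, iterations = iter, residual = resid)
}

#' Stationary distribution of a QBD chain
#'
#' Solves the boundary balance equations together with the geometric tail
#' \eqn{\pi_{b+k} = \pi_b R^k} and the normalization
#' \eqn{\sum_l \pi_l \mathbf{1} = 1}.
#'
#' @param chain A `qbd_chain`.
#' @param r The rate matrix from [solve_r_matrix()].
#' @return An object of class `qbd_stationary` with elements
#'   `boundary_probs` (list of probability vectors for levels `0..b-1`),
#'   `pi_rep` (probability vector of the first repeating level),
#'   `rate_matrix_r`, and `norm_check`.
#' @export
stationary_distribution <- function(chain, r) {
  bnd <- chain$boundary
  b <- length(bnd)
  m <- nrow(chain$A1)
  sizes <- c(vapply(bnd, function(l) nrow(l$local), integer(1)), m)
  offs <- cumsum(c(0L, sizes))
  N <- sum(sizes)
  blk <- function(l) (offs[l + 1L] + 1L):offs[l + 2L]  # l = 0-based level

  down_of <- function(l) {
    # down block out of level l (1 <= l <= b)
    if (l <= b - 1L) bnd[[l + 1L]]$down else chain$first_down
  }

  G <- matrix(0, N, N)
  # balance equations, one column set per target level
  for (tgt in 0:b) {
    cols <- blk(tgt)
    if (tgt < b) {
      loc <- bnd[[tgt + 1L]]$local
      G[blk(tgt), cols] <- G[blk(tgt), cols] + loc
    } else {
      G[blk(b), cols] <- G[blk(b), cols] + chain$A1 + r %*% chain$A2
    }
    if (tgt > 0) {
      up <- if (tgt - 1L < b) bnd[[tgt]]$up else chain$A0
      G[blk(tgt - 1L), cols] <- G[blk(tgt - 1L), cols] + up
    }
    if (tgt < b) {
      G[blk(tgt + 1L), cols] <- G[blk(tgt + 1L), cols] + down_of(tgt + 1L)
    }
  }
  # replace the first balance equation with normalization
  Iminus <- diag(m) - r
  tail_w <- solve(Iminus, rep(1, m))  # (I - R)^{-1} 1
  norm_coef <- c(rep(1, offs[b + 1L]), tail_w)
  G[, 1L] <- norm_coef
  rhs <- c(1, rep(0, N - 1L))
  x <- solve(t(G), rhs)

  if (any(x < -1e-9)) {
    stop("stationary solve produced probabilities below -1e-9; chain is ",
         "ill-conditioned", call. = FALSE)
  }
  x[x < 0] <- 0

  boundary_probs <- lapply(seq_len(b), function(l) x[blk(l - 1L)])
  pi_rep <- x[blk(b)]
  norm_check <- sum(unlist(boundary_probs)) + sum(pi_rep * tail_w)
  if (abs(norm_check - 1) > 1e-8) {
    stop("normalization check failed: total probability = ",
         format(norm_check), call. = FALSE)
  }
  structure(
    list(boundary_probs = boundary_probs, pi_rep = pi_rep,
         rate_matrix_r = r, first_rep_level = b,
         norm_check = norm_check, phase_labels = chain$phase_labels,
         class_rates = chain$class_rates),
    class = "qbd_stationary"
  )
}

#' Mean number of tagged-class images in the system
#'
#' Computed in closed form from the boundary probabilities and the
#' geometric tail, \eqn{L = \sum_{l<b} l\,\pi_l \mathbf{1} + \pi_b [\,b
#' (I-R)^{-1} + R (I-R)^{-2}\,] \mathbf{1}}, not by truncated summation.
#'
#' @param dist A `qbd_stationary`.
#' @return Mean number of images (a scalar).
#' @export
mean_number_in_class <- function(dist) {
  b <- dist$first_rep_level
  L <- 0
  for (l in seq_len(b)) {
    L <- L + (l - 1L) * sum(dist$boundary_probs[[l]])
  }
  R <- dist$rate_matrix_r
  m <- nrow(R)
  I <- diag(m)
  inv1 <- solve(I - R, rep(1, m))          # (I-R)^{-1} 1
  inv2 <- solve(I - R, inv1)               # (I-R)^{-2} 1
  L + sum(dist$pi_rep * (b * inv1 + as.numeric(R %*% inv2)))
}

#' Probability that the system holds a given number of tagged images
#'
#' @param dist A `qbd_stationary`.
#' @param levels Integer vector of level indices (0-based counts).
#' @return Numeric vector of level probabilities.
#' @export
level_probability <- function(dist, levels) {
  b <- dist$first_rep_level
  R <- dist$rate_matrix_r
  vapply(levels, function(l) {
    if (l < b) {
      sum(dist$boundary_probs[[l + 1L]])
    } else {
      Rk <- diag(nrow(R))
      k <- l - b
      while (k > 0) { Rk <- Rk %*% R; k <- k - 1L }
      sum(dist$pi_rep %*% Rk)
    }
  }, numeric(1))
}

#' Mean waits from a solved distribution via Little's law
#'
#' \eqn{W = L/\lambda_j} and \eqn{W_q = W - 1/\mu_j}. A class with
#' `lambda_j = 0` has its queue wait defined as 0 so that downstream
#' sensitivity/specificity weighting of an empty class stays well-defined.
#'
#' @param dist A `qbd_stationary`, or a bare mean count `L`.
#' @param lambda_j,mu_j Arrival and service rate (per minute) of the class.
#' @return A one-row tibble with `l_mean` (images), `w_response` and
#'   `w_queue` (minutes).
#' @export
wait_from_distribution <- function(dist, lambda_j, mu_j) {
  L <- if (inherits(dist, "qbd_stationary")) mean_number_in_class(dist) else dist
  if (lambda_j <= 0) {
    return(tibble::tibble(l_mean = 0, w_response = 0, w_queue = 0))
  }
  W <- L / lambda_j
  Wq <- W - 1 / mu_j
  if (Wq < -1e-9) {
    stop("negative queue wait (", format(Wq), " min) signals an upstream ",
         "solver defect", call. = FALSE)
  }
  tibble::tibble(l_mean = L, w_response = W, w_queue = max(Wq, 0))
}

#' Solve a QBD chain end to end
#'
#' Runs [solve_r_matrix()] and [stationary_distribution()] and extracts
#' the tagged-class mean wait.
#'
#' @param chain A `qbd_chain` with `class_rates` set.
#' @param tol Convergence tolerance for the R iteration.
#' @return An object of class `qbd_solution`: the stationary object plus
#'   `wait` (tibble from [wait_from_distribution()]) and solver
#'   diagnostics.
#' @export
solve_qbd <- function(chain, tol = 1e-12) {
  R <- solve_r_matrix(chain, tol = tol)
  dist <- stationary_distribution(chain, R)
  wait <- wait_from_distribution(dist, chain$class_rates[["lambda"]],
                                 chain$class_rates[["mu"]])
  structure(
    list(dist = dist, wait = wait,
         iterations = attr(R, "iterations"), residual = attr(R, "residual"),
         spectral_radius = spectral_radius(R)),
    class = "qbd_solution"
  )
}

#' @export
print.qbd_solution <- function(x, ...) {
  cat(sprintf("<qbd_solution> W_q = %.6g min (L = %.6g); R iterations %d, residual %.2e\n",
              x$wait$w_queue, x$wait$l_mean, x$iterations, x$residual))
  invisible(x)
}

#' Tidy a solved QBD chain
#'
#' @param x A `qbd_solution`.
#' @param levels Which level probabilities to report (default `0:20`).
#' @param ... Unused.
#' @return A tibble with `level` and `probability`.
#' @method tidy qbd_solution
#' @export
tidy.qbd_solution <- function(x, levels = 0:20, ...) {
  tibble::tibble(level = levels,
                 probability = level_probability(x$dist, levels))
}

#' @method glance qbd_solution
#' @export
glance.qbd_solution <- function(x, ...) {
  tibble::tibble(
    l_mean = x$wait$l_mean, w_queue = x$wait$w_queue,
    norm_check = x$dist$norm_check, spectral_radius = x$spectral_radius,
    iterations = x$iterations, residual = x$residual
  )
}
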