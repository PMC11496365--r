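#' Describe a radiology reading-queue scenario
#'
#' Bundles every parameter of the clinical workflow that the queueing models
#' and the simulator consume: the interrupting-image fraction, disease
#' prevalence among non-interrupting images, the CADt operating point
#' (sensitivity/specificity), staffing, mean read times, and the offered
#' load given either as a total arrival rate or as a traffic intensity.
#'
#' All times are mean read times in minutes; they are inverted into service
#' rates (per minute) internally. Exactly one of `rho` and `lambda` must be
#' supplied. `rho` is the traffic intensity \eqn{\rho = \lambda/(\mu
#' N_{rad})}, where \eqn{1/\mu} is the arrival-fraction-weighted mean read
#' time (see [lambda_from_rho()]).
#'
#' @param prevalence Disease prevalence \eqn{\pi} among non-interrupting
#'   images, in (0, 1).
#' @param se,sp CADt sensitivity and specificity, each in \[0, 1\].
#' @param f Fraction of interrupting images among all images, in \[0, 1).
#' @param n_rad Number of radiologists on-site (integer >= 1).
#' @param read_time_interrupting,read_time_diseased,read_time_nondiseased
#'   Mean read times \eqn{1/\mu_f}, \eqn{1/\mu_D}, \eqn{1/\mu_{ND}} in
#'   minutes (> 0).
#' @param rho Traffic intensity in (0, 1). Mutually exclusive with `lambda`.
#' @param lambda Total Poisson arrival rate in images/minute (> 0).
#'   Mutually exclusive with `rho`.
#'
#' @return A validated object of class `workflow_config`.
#' @examples
#' cfg <- workflow_config(prevalence = 0.1, se = 0.95, sp = 0.89, rho = 0.8)
#' cfg
#' derive_rates(cfg)
#' @seealso [derive_rates()], [compute_waits()], [evaluate_cadt()]
#' @export
workflow_config <- function(prevalence, se, sp,
                            f = 0, n_rad = 1L,
                            read_time_interrupting = 5,
                            read_time_diseased = 10,
                            read_time_nondiseased = 10,
                            rho = NULL, lambda = NULL) {
  cfg <- structure(
    list(
      f = f, prevalence = prevalence, se = se, sp = sp,
      n_rad = n_rad,
      read_time_interrupting = read_time_interrupting,
      read_time_diseased = read_time_diseased,
      read_time_nondiseased = read_time_nondiseased,
      rho = rho, lambda = lambda
    ),
    class = "workflow_config"
  )
  validate_config(cfg)
}

#' Validate a workflow configuration
#'
#' Checks every invariant a scenario must satisfy before the models accept
#' it: probabilities in range, strictly positive read times, `f < 1` so the
#' non-interrupting stream is non-empty, an integer `n_rad >= 1`, and
#' exactly one of `rho` (in (0, 1)) or `lambda` (> 0).
#'
#' @param cfg A `workflow_config` or a bare list with the same fields.
#' @return The normalized `workflow_config`, invisibly classed; errors on
#'   any violated invariant.
#' @export
validate_config <- function(cfg) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    as.numeric(x)
  }
  cfg$f <- num1(cfg$f, "f")
  cfg$prevalence <- num1(cfg$prevalence, "prevalence")
  cfg$se <- num1(cfg$se, "se")
  cfg$sp <- num1(cfg$sp, "sp")
  cfg$read_time_interrupting <- num1(cfg$read_time_interrupting, "read_time_interrupting")
  cfg$read_time_diseased <- num1(cfg$read_time_diseased, "read_time_diseased")
  cfg$read_time_nondiseased <- num1(cfg$read_time_nondiseased, "read_time_nondiseased")

  if (cfg$f < 0 || cfg$f >= 1) {
    stop("`f` must lie in [0, 1): the non-interrupting stream may not be empty",
         call. = FALSE)
  }
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) {
    stop("`prevalence` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (cfg$se < 0 || cfg$se > 1) stop("`se` must lie in [0, 1]", call. = FALSE)
  if (cfg$sp < 0 || cfg$sp > 1) stop("`sp` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(cfg$n_rad) || length(cfg$n_rad) != 1L ||
      cfg$n_rad < 1 || cfg$n_rad != round(cfg$n_rad)) {
    stop("`n_rad` must be an integer >= 1", call. = FALSE)
  }
  cfg$n_rad <- as.integer(cfg$n_rad)
  for (nm in c("read_time_interrupting", "read_time_diseased",
               "read_time_nondiseased")) {
    if (cfg[[nm]] <= 0) {
      stop("`", nm, "` must be a strictly positive time in minutes",
           call. = FALSE)
    }
  }
  has_rho <- !is.null(cfg$rho)
  has_lambda <- !is.null(cfg$lambda)
  if (has_rho == has_lambda) {
    stop("supply exactly one of `rho` and `lambda`", call. = FALSE)
  }
  if (has_rho) {
    cfg$rho <- num1(cfg$rho, "rho")
    if (cfg$rho <= 0 || cfg$rho >= 1) {
      stop("`rho` must lie in (0, 1): the system must be stable", call. = FALSE)
    }
  } else {
    cfg$lambda <- num1(cfg$lambda, "lambda")
    if (cfg$lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  }
  structure(cfg, class = "workflow_config")
}

#' @export
print.workflow_config <- function(x, ...) {
  cat("<workflow_config>\n")
  cat(sprintf("  prevalence: %g  Se: %g  Sp: %g  f: %g  n_rad: %d\n",
              x$prevalence, x$se, x$sp, x$f, x$n_rad))
  cat(sprintf("  read times (min): interrupting %g, diseased %g, non-diseased %g\n",
              x$read_time_interrupting, x$read_time_diseased,
              x$read_time_nondiseased))
  if (!is.null(x$rho)) {
    cat(sprintf("  load: rho = %g (lambda = %.6g /min)\n", x$rho,
                lambda_from_rho(x)))
  } else {
    cat(sprintf("  load: lambda = %g /min\n", x$lambda))
  }
  invisible(x)
}

#' Read a workflow configuration from a YAML or JSON file
#'
#' The file uses the keys `f`, `prevalence`, `se`, `sp`, `n_rad`,
#' `read_time_interrupting_min`, `read_time_diseased_min`,
#' `read_time_nondiseased_min`, and exactly one of `rho` or
#' `lambda_per_min`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `workflow_config`.
#' @export
read_workflow_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("prevalence", "se", "sp")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("config file is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  workflow_config(
    prevalence = raw$prevalence, se = raw$se, sp = raw$sp,
    f = raw$f %||% 0,
    n_rad = raw$n_rad %||% 1L,
    read_time_interrupting = raw$read_time_interrupting_min %||% 5,
    read_time_diseased = raw$read_time_diseased_min %||% 10,
    read_time_nondiseased = raw$read_time_nondiseased_min %||% 10,
    rho = raw$rho, lambda = raw$lambda_per_min
  )
}

#' Total arrival rate implied by a traffic intensity
#'
#' Converts \eqn{\rho} into \eqn{\lambda} through \eqn{\rho = \lambda /
#' (\mu_{eff} N_{rad})}, where the effective service rate is the harmonic
#' combination of the class read times weighted by arrival fractions:
#' \deqn{1/\mu_{eff} = f/\mu_f + (1-f)\left(\pi/\mu_D +
#'   (1-\pi)/\mu_{ND}\right),}
#' i.e. \eqn{1/\mu_{eff}} is the overall mean read time of an arriving
#' image. With 10-minute reads, no interruptions and one radiologist,
#' `rho = 0.8` gives `lambda = 0.08`/min.
#'
#' @param cfg A validated `workflow_config` whose load is given as `rho`.
#' @return The total arrival rate in images/minute.
#' @export
lambda_from_rho <- function(cfg) {
  cfg <- validate_config(cfg)
  if (is.null(cfg$rho)) {
    stop("`cfg` specifies `lambda` directly; nothing to convert", call. = FALSE)
  }
  mean_read <- cfg$f * cfg$read_time_interrupting +
    (1 - cfg$f) * (cfg$prevalence * cfg$read_time_diseased +
                     (1 - cfg$prevalence) * cfg$read_time_nondiseased)
  cfg$rho * cfg$n_rad / mean_read
}

config_lambda <- function(cfg) {
  if (!is.null(cfg$lambda)) cfg$lambda else lambda_from_rho(cfg)
}

config_rho <- function(cfg) {
  mean_read <- cfg$f * cfg$read_time_interrupting +
    (1 - cfg$f) * (cfg$prevalence * cfg$read_time_diseased +
                     (1 - cfg$prevalence) * cfg$read_time_nondiseased)
  config_lambda(cfg) * mean_read / cfg$n_rad
}

#' Positive and negative predictive values
#'
#' Bayes' rule on the 2x2 diagnostic table:
#' \deqn{PPV = \frac{\pi Se}{\pi Se + (1-\pi)(1-Sp)}, \qquad
#'       NPV = \frac{(1-\pi) Sp}{(1-\pi) Sp + \pi (1-Se)}.}
#' When a denominator is zero (the corresponding AI call never occurs) the
#' value is defined as 0 so that downstream weighting by `se` or `1 - se`
#' nullifies the empty class instead of propagating `NaN`.
#'
#' @param pi Disease prevalence in (0, 1). Vectorized.
#' @param se,sp Sensitivity and specificity in \[0, 1\]. Vectorized.
#' @return A tibble with columns `ppv` and `npv`.
#' @examples
#' ppv_npv(0.1, 0.95, 0.89)
#' @export
ppv_npv <- function(pi, se, sp) {
  num_p <- pi * se
  den_p <- pi * se + (1 - pi) * (1 - sp)
  num_n <- (1 - pi) * sp
  den_n <- (1 - pi) * sp + pi * (1 - se)
  tibble::tibble(
    ppv = ifelse(den_p > 0, num_p / den_p, 0),
    npv = ifelse(den_n > 0, num_n / den_n, 0)
  )
}

#' Derive every per-class arrival and service rate
#'
#' Splits the total Poisson stream into interrupting / non-interrupting and
#' (with a CADt) AI-positive / AI-negative classes, and computes each
#' class's mean read rate. The AI-class rates mix the diseased and
#' non-diseased read times by the predictive values:
#' \deqn{\lambda_+ = [\pi Se + (1-\pi)(1-Sp)]\,\lambda_{nonf}/(1-f), \quad
#'       1/\mu_+ = PPV/\mu_D + (1-PPV)/\mu_{ND},}
#' and analogously for the AI-negative class with NPV. Load is conserved:
#' \eqn{\lambda_+/\mu_+ + \lambda_-/\mu_- = \lambda_{nonf}/\mu_{nonf}}.
#'
#' @param cfg A validated `workflow_config`.
#' @return A one-row tibble with columns `lambda_total`, `lambda_f`,
#'   `lambda_nonf`, `lambda_pos`, `lambda_neg` (arrivals/minute), `mu_f`,
#'   `mu_d`, `mu_nd`, `mu_nonf`, `mu_pos`, `mu_neg` (reads/minute), `ppv`,
#'   `npv`, and `n_rad`.
#' @examples
#' derive_rates(workflow_config(prevalence = 0.1, se = 0.95, sp = 0.89,
#'                              rho = 0.8))
#' @export
derive_rates <- function(cfg) {
  cfg <- validate_config(cfg)
  lambda <- config_lambda(cfg)
  pi <- cfg$prevalence
  pv <- ppv_npv(pi, cfg$se, cfg$sp)

  mu_d <- 1 / cfg$read_time_diseased
  mu_nd <- 1 / cfg$read_time_nondiseased
  mu_nonf <- 1 / (pi / mu_d + (1 - pi) / mu_nd)
  mu_pos <- 1 / (pv$ppv / mu_d + (1 - pv$ppv) / mu_nd)
  mu_neg <- 1 / ((1 - pv$npv) / mu_d + pv$npv / mu_nd)

  lambda_nonf <- (1 - cfg$f) * lambda
  tibble::tibble(
    prevalence = pi,
    lambda_total = lambda,
    lambda_f = cfg$f * lambda,
    lambda_nonf = lambda_nonf,
    lambda_pos = (pi * cfg$se + (1 - pi) * (1 - cfg$sp)) * lambda_nonf,
    lambda_neg = (pi * (1 - cfg$se) + (1 - pi) * cfg$sp) * lambda_nonf,
    mu_f = 1 / cfg$read_time_interrupting,
    mu_d = mu_d,
    mu_nd = mu_nd,
    mu_nonf = mu_nonf,
    mu_pos = mu_pos,
    mu_neg = mu_neg,
    ppv = pv$ppv,
    npv = pv$npv,
    n_rad = cfg$n_rad
  )
}

#' ROC operating point of a CADt device
#'
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @return A tibble with `tpr` (= `se`) and `fpr` (= `1 - sp`).
#' @export
operating_point <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  tibble::tibble(tpr = se, fpr = 1 - sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
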