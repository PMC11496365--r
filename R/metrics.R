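#' @title Wait-time-saving performance metrics
#'
#' @description
#' The per-class waits are combined into subgroup means. Without a CADt,
#' arrivals are served in order, so the diseased and non-diseased means
#' both equal the non-interrupting wait. With a CADt, the diseased mean
#' mixes the AI-positive and AI-negative waits by sensitivity (the
#' true-positive fraction of the diseased subgroup), and the non-diseased
#' mean by `1 - Sp` and `Sp`. The headline metric is the signed
#' difference \eqn{\delta W_D = W_D^{CADt} - W_D^{no\,CADt}}: negative
#' values are time savings for diseased patients.
#'
#' @name metrics
NULL

#' Mean diseased wait with a CADt in place
#'
#' \eqn{W_D^{CADt} = W_+ \cdot Se + W_- \cdot (1 - Se)}: true positives
#' wait like the AI-positive class, false negatives like the AI-negative
#' class.
#'
#' @param w_pos,w_neg Mean AI-positive / AI-negative queue waits
#'   (minutes).
#' @param se Sensitivity in \[0, 1\]. Vectorized.
#' @return Mean diseased queue wait in minutes.
#' @examples
#' diseased_wait_with_cadt(1.8371, 49.186, 0.95)
#' @export
diseased_wait_with_cadt <- function(w_pos, w_neg, se) {
  stopifnot(all(w_pos >= 0), all(w_neg >= 0), all(se >= 0 & se <= 1))
  w_pos * se + w_neg * (1 - se)
}

#' Mean non-diseased wait with a CADt in place
#'
#' \eqn{W_{ND}^{CADt} = W_+ \cdot (1 - Sp) + W_- \cdot Sp}: false
#' positives wait like the AI-positive class, true negatives like the
#' AI-negative class.
#'
#' @inheritParams diseased_wait_with_cadt
#' @param sp Specificity in \[0, 1\]. Vectorized.
#' @return Mean non-diseased queue wait in minutes.
#' @export
nondiseased_wait_with_cadt <- function(w_pos, w_neg, sp) {
  stopifnot(all(w_pos >= 0), all(w_neg >= 0), all(sp >= 0 & sp <= 1))
  w_pos * (1 - sp) + w_neg * sp
}

#' Combine scenario waits into the time-saving metrics
#'
#' @param waits A tibble from [compute_waits()] (rows for the
#'   non-interrupting, AI-positive and AI-negative classes).
#' @param se,sp Sensitivity and specificity used to weigh the classes;
#'   default to the configuration attached to `waits`.
#' @return A one-row tibble with `w_d_no_cadt`, `w_d_cadt`, `delta_w_d`,
#'   `w_nd_no_cadt`, `w_nd_cadt`, `delta_w_nd` (minutes; negative deltas
#'   are savings) and the supplementary ratio `ratio_d =
#'   w_d_cadt / w_d_no_cadt`.
#' @export
delta_metrics <- function(waits, se = NULL, sp = NULL) {
  cfg <- attr(waits, "config")
  se <- se %||% cfg$se
  sp <- sp %||% cfg$sp
  w_nonf <- waits$w_queue[waits$class == "nonf"]
  w_pos <- waits$w_queue[waits$class == "pos"]
  w_neg <- waits$w_queue[waits$class == "neg"]
  w_d_cadt <- diseased_wait_with_cadt(w_pos, w_neg, se)
  w_nd_cadt <- nondiseased_wait_with_cadt(w_pos, w_neg, sp)
  tibble::tibble(
    w_d_no_cadt = w_nonf,
    w_d_cadt = w_d_cadt,
    delta_w_d = w_d_cadt - w_nonf,
    w_nd_no_cadt = w_nonf,
    w_nd_cadt = w_nd_cadt,
    delta_w_nd = w_nd_cadt - w_nonf,
    ratio_d = if (w_nonf > 0) w_d_cadt / w_nonf else NA_real_
  )
}

#' Evaluate a CADt device end to end
#'
#' Runs the full theoretical pipeline for one configuration: rates, busy
#' periods, chains, matrix-geometric solve, Little's law, and the
#' sensitivity/specificity-weighted metrics.
#'
#' @param cfg A `workflow_config`.
#' @param model Passed to [compute_waits()].
#' @return A one-row tibble with the operating point (`se`, `sp`, `fpr`,
#'   `tpr`), the per-class waits (`w_q_nonf`, `w_q_pos`, `w_q_neg`), and
#'   every column of [delta_metrics()].
#' @examples
#' cfg <- workflow_config(prevalence = 0.1, se = 0.95, sp = 0.89, rho = 0.8)
#' evaluate_cadt(cfg)
#' @export
evaluate_cadt <- function(cfg, model = "auto") {
  cfg <- validate_config(cfg)
  waits <- compute_waits(cfg, model = model)
  dplyr::bind_cols(
    tibble::tibble(
      se = cfg$se, sp = cfg$sp, fpr = 1 - cfg$sp, tpr = cfg$se,
      w_q_nonf = waits$w_queue[waits$class == "nonf"],
      w_q_pos = waits$w_queue[waits$class == "pos"],
      w_q_neg = waits$w_queue[waits$class == "neg"]
    ),
    delta_metrics(waits)
  )
}
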