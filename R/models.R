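#' @title Reading-queue Markov chains for both scenarios and both models
#'
#' @description
#' Four chain families cover the two workflow models and two scenarios.
#' Model 1 assumes equal diseased/non-diseased read rates (so the
#' non-interrupting, AI-positive and AI-negative classes all read at
#' \eqn{\mu_{nonf}}) and supports one or two radiologists analytically.
#' Model 2 allows \eqn{\mu_D \neq \mu_{ND}} with a single radiologist;
#' its states carry the disease status of the image in service and, in
#' truncated states, the status the radiologist must resume
#' (preemptive-resume memory).
#'
#' All chains are level-structured in the tagged-class count and are
#' solved by [solve_qbd()]; higher-priority sojourns are replaced by
#' Erlang-Coxian busy periods (see [busy_periods]).
#'
#' @name markov_models
NULL

# assemble a homogeneous-phase QBD from off-diagonal local rates (Loc),
# an up block U (arrivals of the tagged class), the repeating down block
# D2 (two in service where applicable), the level-1 down block D1, and the
# level-0 correction (no tagged service).  All blocks share one phase
# space; level 0 may instead be given explicitly via `level0`.
assemble_qbd <- function(Loc, U, D2, D1, lambda_j, mu_j, phase_labels,
                         level0 = NULL, U0 = NULL, level_meaning) {
  m <- nrow(Loc)
  diag_tot <- function(extra) -(rowSums(Loc) + rowSums(U) + extra)
  A1 <- Loc + diag(diag_tot(rowSums(D2)), m)
  L1 <- Loc + diag(diag_tot(rowSums(D1)), m)
  boundary <- list()
  if (is.null(level0)) {
    L0 <- Loc + diag(diag_tot(0), m)
    boundary[[1]] <- list(local = L0, up = U)
  } else {
    boundary[[1]] <- list(local = level0, up = U0)
  }
  boundary[[2]] <- list(local = L1, up = U, down = D1)
  qbd_chain(boundary = boundary, A0 = U, A1 = A1, A2 = D2,
            first_down = D2, phase_labels = phase_labels,
            class_rates = c(lambda = lambda_j, mu = mu_j),
            level_meaning = level_meaning)
}

# two-priority chain shared by Model 1's without-CADt scenario and (after
# the lambda/mu substitution) its AI-positive scenario.
build_model1_two_class <- function(lambda_cls, mu_cls, lambda_f, mu_f,
                                   n_rad, level_meaning) {
  if (!n_rad %in% c(1L, 2L)) {
    stop("analytic Model 1 chains support n_rad in {1, 2}; use the ",
         "simulator for larger teams", call. = FALSE)
  }
  util <- (lambda_f / mu_f + lambda_cls / mu_cls) / n_rad
  if (util >= 1 - 1e-9) {
    stop("unstable configuration: utilization ", format(util), call. = FALSE)
  }
  if (lambda_f > 0) {
    bp <- fit_ec(unname(mm1_busy_period_moments(lambda_f, n_rad * mu_f)))
    g <- ec_transient_generator(bp)
    k <- nrow(g$S)
  } else {
    k <- 0L
  }
  if (n_rad == 1L) {
    # phases: free, busy-period phases
    m <- 1L + k
    Loc <- matrix(0, m, m)
    if (k > 0) {
      Loc[1L, 2L] <- lambda_f
      Loc[2:m, 2:m] <- g$S - diag(diag(g$S), k)
      Loc[2:m, 1L] <- g$absorb
    }
    labels <- c("free", if (k > 0) paste0("bp", 1:k))
    D <- matrix(0, m, m); D[1L, 1L] <- mu_cls
    chain <- assemble_qbd(Loc, diag(lambda_cls, m), D2 = D, D1 = D,
                          lambda_cls, mu_cls, labels, level_meaning = level_meaning)
    return(chain)
  }
  # n_rad == 2: phases nf=0, nf=1, busy-period phases
  m <- 2L + k
  Loc <- matrix(0, m, m)
  Loc[1L, 2L] <- lambda_f
  Loc[2L, 1L] <- mu_f
  if (k > 0) {
    Loc[2L, 3L] <- lambda_f
    Loc[3:m, 3:m] <- g$S - diag(diag(g$S), k)
    Loc[3:m, 2L] <- g$absorb
  }
  labels <- c("nf0", "nf1", if (k > 0) paste0("bp", 1:k))
  D2 <- matrix(0, m, m); D2[1L, 1L] <- 2 * mu_cls; D2[2L, 2L] <- mu_cls
  D1 <- matrix(0, m, m); D1[1L, 1L] <- mu_cls; D1[2L, 2L] <- mu_cls
  assemble_qbd(Loc, diag(lambda_cls, m), D2 = D2, D1 = D1,
               lambda_cls, mu_cls, labels, level_meaning = level_meaning)
}

#' Model 1 chain without a CADt device
#'
#' Levels count non-interrupting images; phases track the interrupting
#' work (none, one, or an Erlang-Coxian busy period during which no
#' radiologist is free). With two radiologists the level-1 departure rate
#' is \eqn{\mu_{nonf}} and \eqn{2\mu_{nonf}} from level 2 on.
#'
#' @param rates A one-row tibble from [derive_rates()].
#' @param n_rad Radiologist count (1 or 2 analytically).
#' @return A `qbd_chain` whose tagged class is the non-interrupting
#'   stream.
#' @export
build_model1_without_cadt <- function(rates, n_rad = rates$n_rad) {
  build_model1_two_class(rates$lambda_nonf, rates$mu_nonf,
                         rates$lambda_f, rates$mu_f, as.integer(n_rad),
                         "non-interrupting images n_nonf")
}

#' Model 1 chain for the AI-positive class
#'
#' Under preemptive-resume priority the AI-positive class never sees
#' AI-negative work, so its chain is the without-CADt chain with
#' \eqn{\lambda_{nonf} \to \lambda_+} and \eqn{\mu_{nonf} \to \mu_+}.
#'
#' @inheritParams build_model1_without_cadt
#' @return A `qbd_chain` for the AI-positive class.
#' @export
build_model1_ai_positive <- function(rates, n_rad = rates$n_rad) {
  build_model1_two_class(rates$lambda_pos, rates$mu_pos,
                         rates$lambda_f, rates$mu_f, as.integer(n_rad),
                         "AI-positive images n_+")
}

#' Model 1 chain for the AI-negative class
#'
#' For one radiologist the interrupting and AI-positive streams aggregate
#' into a single M/G/1-type busy period (hyperexponential services)
#' entered at rate \eqn{\lambda_f + \lambda_+}. For two radiologists the
#' six conditional busy periods B1-B6 from [busy_period_set_model1()]
#' connect the three free-server phases (0,0), (0,1), (1,0); truncated
#' high-priority states are duplicated per end state and weighted by the
#' conditional end probabilities.
#'
#' @inheritParams build_model1_without_cadt
#' @param busy Optional precomputed busy-period tibble (two-radiologist
#'   case); computed on demand otherwise.
#' @return A `qbd_chain` for the AI-negative class.
#' @export
build_model1_ai_negative <- function(rates, n_rad = rates$n_rad,
                                     busy = NULL) {
  n_rad <- as.integer(n_rad)
  lf <- rates$lambda_f; mf <- rates$mu_f
  lp <- rates$lambda_pos; mp <- rates$mu_pos
  ln <- rates$lambda_neg; mn <- rates$mu_neg
  util <- (lf / mf + lp / mp + ln / mn) / n_rad
  if (util >= 1 - 1e-9) {
    stop("unstable configuration: utilization ", format(util), call. = FALSE)
  }
  if (n_rad == 1L) {
    lam_h <- lf + lp
    if (lam_h > 0) {
      s <- mixture_moments(c(lf, lp), list(exp_moments(mf), exp_moments(mp)))
      bpm <- mg1_busy_period_moments(lam_h, s)
      bp <- fit_ec(unname(bpm))
      g <- ec_transient_generator(bp)
      k <- nrow(g$S)
    } else {
      k <- 0L
    }
    m <- 1L + k
    Loc <- matrix(0, m, m)
    if (k > 0) {
      Loc[1L, 2L] <- lam_h
      Loc[2:m, 2:m] <- g$S - diag(diag(g$S), k)
      Loc[2:m, 1L] <- g$absorb
    }
    labels <- c("free", if (k > 0) paste0("bp", 1:k))
    D <- matrix(0, m, m); D[1L, 1L] <- mn
    return(assemble_qbd(Loc, diag(ln, m), D2 = D, D1 = D, ln, mn, labels,
                        level_meaning = "AI-negative images n_-"))
  }
  if (n_rad != 2L) {
    stop("analytic Model 1 chains support n_rad in {1, 2}; use the ",
         "simulator for larger teams", call. = FALSE)
  }
  if (is.null(busy)) busy <- busy_period_set_model1(rates, n_rad = 2L)

  # phase bookkeeping: free phases first, then one block per busy period
  has_pos <- lp > 0
  has_f <- lf > 0
  free <- c("(0,0)", if (has_pos) "(0,1)", if (has_f) "(1,0)")
  keep_bp <- vapply(seq_len(nrow(busy)), function(r) {
    lab <- busy$label[r]
    switch(lab,
           B1 = , B2 = has_pos,
           B3 = , B4 = has_pos && has_f,
           B5 = , B6 = has_f,
           FALSE)
  }, logical(1))
  busy <- busy[keep_bp, , drop = FALSE]
  # renormalize end probabilities per start state among retained periods
  busy <- dplyr::group_by(busy, .data$start_state)
  busy <- dplyr::mutate(busy, cond_prob = .data$cond_prob / sum(.data$cond_prob))
  busy <- dplyr::ungroup(busy)

  gens <- lapply(busy$fit, ec_transient_generator)
  kbp <- vapply(gens, function(g) nrow(g$S), integer(1))
  n_free <- length(free)
  bp_off <- n_free + cumsum(c(0L, kbp[-length(kbp)]))
  m <- n_free + sum(kbp)
  ph <- function(nm) match(nm, free)

  Loc <- matrix(0, m, m)
  enter <- function(from, rate, rowsel) {
    # rate split across the busy periods starting at a given state
    for (r in which(rowsel)) {
      Loc[from, bp_off[r] + 1L] <<- Loc[from, bp_off[r] + 1L] +
        rate * busy$cond_prob[r]
    }
  }
  if (has_pos) {
    Loc[ph("(0,0)"), ph("(0,1)")] <- lp
    Loc[ph("(0,1)"), ph("(0,0)")] <- mp
    enter(ph("(0,1)"), lp, busy$start_state == "(0,2)")
    if (has_f) enter(ph("(0,1)"), lf, busy$start_state == "(1,1)")
  }
  if (has_f) {
    Loc[ph("(0,0)"), ph("(1,0)")] <- lf
    Loc[ph("(1,0)"), ph("(0,0)")] <- mf
    enter(ph("(1,0)"), lf, busy$start_state == "(2,0)")
    if (has_pos) enter(ph("(1,0)"), lp, busy$start_state == "(1,1)")
  }
  for (r in seq_len(nrow(busy))) {
    sel <- bp_off[r] + seq_len(kbp[r])
    Loc[sel, sel] <- gens[[r]]$S - diag(diag(gens[[r]]$S), kbp[r])
    tgt <- if (busy$end_state[r] == "(0,1)") ph("(0,1)") else ph("(1,0)")
    Loc[sel, tgt] <- gens[[r]]$absorb
  }
  labels <- c(free, unlist(lapply(seq_len(nrow(busy)), function(r) {
    paste0(busy$label[r], "_", seq_len(kbp[r]))
  })))
  D2 <- matrix(0, m, m)
  D2[ph("(0,0)"), ph("(0,0)")] <- 2 * mn
  if (has_pos) D2[ph("(0,1)"), ph("(0,1)")] <- mn
  if (has_f) D2[ph("(1,0)"), ph("(1,0)")] <- mn
  D1 <- D2
  D1[ph("(0,0)"), ph("(0,0)")] <- mn
  assemble_qbd(Loc, diag(ln, m), D2 = D2, D1 = D1, ln, mn, labels,
               level_meaning = "AI-negative images n_-")
}

# shared Model 2 two-priority chain: one radiologist, a tagged class whose
# in-service image is diseased with probability mix_d (read rate mu_d) or
# non-diseased (mu_nd), interrupted by an M/M/1 busy period of the
# interrupting stream.  Truncated states are duplicated per resumed
# disease status so the radiologist resumes the right image.
build_model2_two_class <- function(lambda_cls, mix_d, mu_d, mu_nd,
                                   lambda_f, mu_f, mu_cls, level_meaning) {
  util <- lambda_f / mu_f + lambda_cls / mu_cls
  if (util >= 1 - 1e-9) {
    stop("unstable configuration: utilization ", format(util), call. = FALSE)
  }
  if (lambda_f > 0) {
    bp <- fit_ec(unname(mm1_busy_period_moments(lambda_f, mu_f)))
    g <- ec_transient_generator(bp)
    k <- nrow(g$S)
  } else {
    k <- 0L
  }
  m <- 2L + 2L * k                      # D, ND, bp->D, bp->ND
  labels <- c("serve_D", "serve_ND",
              if (k > 0) c(paste0("bpD", 1:k), paste0("bpND", 1:k)))
  Loc <- matrix(0, m, m)
  if (k > 0) {
    selD <- 2L + 1:k
    selND <- 2L + k + 1:k
    Soff <- g$S - diag(diag(g$S), k)
    Loc[1L, selD[1L]] <- lambda_f
    Loc[2L, selND[1L]] <- lambda_f
    Loc[selD, selD] <- Soff
    Loc[selND, selND] <- Soff
    Loc[selD, 1L] <- g$absorb
    Loc[selND, 2L] <- g$absorb
  }
  D2 <- matrix(0, m, m)
  D2[1L, 1L] <- mu_d * mix_d;  D2[1L, 2L] <- mu_d * (1 - mix_d)
  D2[2L, 1L] <- mu_nd * mix_d; D2[2L, 2L] <- mu_nd * (1 - mix_d)

  m0 <- 1L + k                          # empty, untagged bp phases
  L0 <- matrix(0, m0, m0)
  if (k > 0) {
    sel0 <- 1L + 1:k
    L0[1L, sel0[1L]] <- lambda_f
    L0[sel0, sel0] <- g$S - diag(diag(g$S), k)
    L0[sel0, 1L] <- g$absorb
  }
  U0 <- matrix(0, m0, m)
  U0[1L, 1L] <- lambda_cls * mix_d
  U0[1L, 2L] <- lambda_cls * (1 - mix_d)
  if (k > 0) {
    U0[1L + 1:k, 2L + 1:k] <- diag(lambda_cls * mix_d, k)
    U0[1L + 1:k, 2L + k + 1:k] <- diag(lambda_cls * (1 - mix_d), k)
  }
  L0 <- L0 - diag(rowSums(L0) + rowSums(U0), m0)
  D1 <- matrix(0, m, m0)
  D1[1L, 1L] <- mu_d
  D1[2L, 1L] <- mu_nd

  U <- diag(lambda_cls, m)
  A1 <- Loc - diag(rowSums(Loc) + rowSums(U) + rowSums(D2), m)
  L1 <- Loc - diag(rowSums(Loc) + rowSums(U) + rowSums(D1), m)
  qbd_chain(
    boundary = list(list(local = L0, up = U0),
                    list(local = L1, up = U, down = D1)),
    A0 = U, A1 = A1, A2 = D2, first_down = D2, phase_labels = labels,
    class_rates = c(lambda = lambda_cls, mu = mu_cls),
    level_meaning = level_meaning
  )
}

#' Model 2 chain without a CADt device
#'
#' One radiologist, unequal read rates. States carry the disease status
#' of the non-interrupting image in service; truncated interrupting busy
#' periods are duplicated as "resume diseased" / "resume non-diseased"
#' copies sharing one fitted parameter set, so the radiologist always
#' resumes the interrupted image (preemptive-resume memory).
#'
#' @param rates A one-row tibble from [derive_rates()].
#' @return A `qbd_chain` for the non-interrupting class.
#' @export
build_model2_without_cadt <- function(rates) {
  build_model2_two_class(rates$lambda_nonf, rates$prevalence, rates$mu_d,
                         rates$mu_nd, rates$lambda_f, rates$mu_f,
                         rates$mu_nonf, "non-interrupting images n_nonf")
}

#' Model 2 chain for the AI-positive class
#'
#' The without-CADt Model 2 chain under the substitution
#' \eqn{\lambda_{nonf} \to \lambda_+}, \eqn{\mu_{nonf} \to \mu_+} and
#' \eqn{\pi \to PPV} (the disease mix inside the AI-positive class).
#'
#' @inheritParams build_model2_without_cadt
#' @return A `qbd_chain` for the AI-positive class.
#' @export
build_model2_ai_positive <- function(rates) {
  build_model2_two_class(rates$lambda_pos, rates$ppv, rates$mu_d,
                         rates$mu_nd, rates$lambda_f, rates$mu_f,
                         rates$mu_pos, "AI-positive images n_+")
}

#' Model 2 chain for the AI-negative class
#'
#' One radiologist. Phases carry the disease status `j` of the
#' AI-negative image in service (diseased with probability `1 - NPV`);
#' the three busy periods B1-B3 from [busy_period_set_model2()] are
#' duplicated per resumed status so each returns to the matching `j`.
#' The AI-positive status `i` and the AI-negative status `j` never
#' coexist: one radiologist reads one image at a time.
#'
#' @inheritParams build_model2_without_cadt
#' @param busy Optional precomputed busy-period tibble.
#' @return A `qbd_chain` for the AI-negative class.
#' @export
build_model2_ai_negative <- function(rates, busy = NULL) {
  lf <- rates$lambda_f; lp <- rates$lambda_pos; ln <- rates$lambda_neg
  util <- lf / rates$mu_f + lp / rates$mu_pos + ln / rates$mu_neg
  if (util >= 1 - 1e-9) {
    stop("unstable configuration: utilization ", format(util), call. = FALSE)
  }
  if (is.null(busy)) busy <- busy_period_set_model2(rates)
  mixd <- 1 - rates$npv                 # P(diseased | AI-negative)
  entry_rate <- c(B1 = lf, B2 = lp * rates$ppv, B3 = lp * (1 - rates$ppv))

  nb <- nrow(busy)
  gens <- if (nb > 0) lapply(busy$fit, ec_transient_generator) else list()
  kbp <- vapply(gens, function(g) nrow(g$S), integer(1))
  ktot <- sum(kbp)
  m <- 2L + 2L * ktot
  offD <- 2L + cumsum(c(0L, kbp[-length(kbp)]))      # ->D copies
  offND <- 2L + ktot + cumsum(c(0L, kbp[-length(kbp)]))
  if (nb == 0) { offD <- integer(0); offND <- integer(0) }

  Loc <- matrix(0, m, m)
  for (r in seq_len(nb)) {
    rate <- entry_rate[[busy$label[r]]]
    selD <- offD[r] + seq_len(kbp[r])
    selND <- offND[r] + seq_len(kbp[r])
    Soff <- gens[[r]]$S - diag(diag(gens[[r]]$S), kbp[r])
    Loc[1L, selD[1L]] <- rate
    Loc[2L, selND[1L]] <- rate
    Loc[selD, selD] <- Soff
    Loc[selND, selND] <- Soff
    Loc[selD, 1L] <- gens[[r]]$absorb
    Loc[selND, 2L] <- gens[[r]]$absorb
  }
  labels <- c("serve_D", "serve_ND",
              unlist(lapply(seq_len(nb), function(r)
                paste0(busy$label[r], "D_", seq_len(kbp[r])))),
              unlist(lapply(seq_len(nb), function(r)
                paste0(busy$label[r], "ND_", seq_len(kbp[r])))))
  D2 <- matrix(0, m, m)
  D2[1L, 1L] <- rates$mu_d * mixd;  D2[1L, 2L] <- rates$mu_d * (1 - mixd)
  D2[2L, 1L] <- rates$mu_nd * mixd; D2[2L, 2L] <- rates$mu_nd * (1 - mixd)

  m0 <- 1L + ktot
  off0 <- 1L + cumsum(c(0L, kbp[-length(kbp)]))
  if (nb == 0) off0 <- integer(0)
  L0 <- matrix(0, m0, m0)
  U0 <- matrix(0, m0, m)
  U0[1L, 1L] <- ln * mixd
  U0[1L, 2L] <- ln * (1 - mixd)
  for (r in seq_len(nb)) {
    rate <- entry_rate[[busy$label[r]]]
    sel0 <- off0[r] + seq_len(kbp[r])
    L0[1L, sel0[1L]] <- rate
    L0[sel0, sel0] <- gens[[r]]$S - diag(diag(gens[[r]]$S), kbp[r])
    L0[sel0, 1L] <- gens[[r]]$absorb
    U0[sel0, offD[r] + seq_len(kbp[r])] <- diag(ln * mixd, kbp[r])
    U0[sel0, offND[r] + seq_len(kbp[r])] <- diag(ln * (1 - mixd), kbp[r])
  }
  L0 <- L0 - diag(rowSums(L0) + rowSums(U0), m0)
  D1 <- matrix(0, m, m0)
  D1[1L, 1L] <- rates$mu_d
  D1[2L, 1L] <- rates$mu_nd

  U <- diag(ln, m)
  A1 <- Loc - diag(rowSums(Loc) + rowSums(U) + rowSums(D2), m)
  L1 <- Loc - diag(rowSums(Loc) + rowSums(U) + rowSums(D1), m)
  qbd_chain(
    boundary = list(list(local = L0, up = U0),
                    list(local = L1, up = U, down = D1)),
    A0 = U, A1 = A1, A2 = D2, first_down = D2, phase_labels = labels,
    class_rates = c(lambda = ln, mu = rates$mu_neg),
    level_meaning = "AI-negative images n_-"
  )
}

#' Per-class mean waits for both scenarios
#'
#' End-to-end orchestration: derives rates, computes the busy periods,
#' builds the without-CADt, AI-positive and AI-negative chains, solves
#' each by the matrix-geometric method, and extracts mean queue waits via
#' Little's law. A class with zero arrival rate (a degenerate operating
#' point such as `se = 0`) gets a queue wait of 0 by convention; its
#' weight in the downstream metrics is also 0.
#'
#' @param cfg A `workflow_config`.
#' @param model `"auto"` (default) picks Model 1 when the diseased and
#'   non-diseased read times are equal and Model 2 otherwise; `"1"` or
#'   `"2"` force a model (Model 1 requires equal read times; Model 2
#'   requires one radiologist).
#' @return A tibble with one row per (scenario, class): columns `model`,
#'   `scenario` (`"without_cadt"` / `"with_cadt"`), `class` (`"nonf"`,
#'   `"pos"`, `"neg"`), `lambda`, `mu`, `l_mean`, `w_response`,
#'   `w_queue` (minutes).
#' @examples
#' cfg <- workflow_config(prevalence = 0.1, se = 0.95, sp = 0.89, rho = 0.8)
#' compute_waits(cfg)
#' @export
compute_waits <- function(cfg, model = c("auto", "1", "2")) {
  cfg <- validate_config(cfg)
  model <- match.arg(as.character(model), c("auto", "1", "2"))
  rates <- derive_rates(cfg)
  equal_mu <- cfg$read_time_diseased == cfg$read_time_nondiseased
  if (model == "auto") model <- if (equal_mu) "1" else "2"
  if (model == "1" && !equal_mu) {
    stop("Model 1 requires equal diseased/non-diseased read times; ",
         "use model = \"2\"", call. = FALSE)
  }
  if (model == "2" && cfg$n_rad != 1L) {
    stop("Model 2 supports a single radiologist only; the simulator ",
         "covers larger teams", call. = FALSE)
  }

  zero_wait <- tibble::tibble(l_mean = 0, w_response = 0, w_queue = 0)
  solve_wait <- function(chain) solve_qbd(chain)$wait

  if (model == "1") {
    w_nonf <- solve_wait(build_model1_without_cadt(rates))
    w_pos <- if (rates$lambda_pos > 0) {
      solve_wait(build_model1_ai_positive(rates))
    } else zero_wait
    w_neg <- if (rates$lambda_neg > 0) {
      solve_wait(build_model1_ai_negative(rates))
    } else zero_wait
  } else {
    w_nonf <- solve_wait(build_model2_without_cadt(rates))
    w_pos <- if (rates$lambda_pos > 0) {
      solve_wait(build_model2_ai_positive(rates))
    } else zero_wait
    w_neg <- if (rates$lambda_neg > 0) {
      solve_wait(build_model2_ai_negative(rates))
    } else zero_wait
  }
  waits <- dplyr::bind_rows(w_nonf, w_pos, w_neg)
  out <- dplyr::bind_cols(
    tibble::tibble(
      model = as.integer(model),
      scenario = c("without_cadt", "with_cadt", "with_cadt"),
      class = c("nonf", "pos", "neg"),
      lambda = c(rates$lambda_nonf, rates$lambda_pos, rates$lambda_neg),
      mu = c(rates$mu_nonf, rates$mu_pos, rates$mu_neg)
    ),
    waits
  )
  attr(out, "config") <- cfg
  out
}
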