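#' The marginal-majority lock-in criterion
#'
#' A binary choice process whose influence curve has a jump M at popularity
#' 1/2 and inherent appeal difference d = 1 - 2 g(0.5) is guaranteed
#' lock-in-prone whenever M > d: the right limit of the curve at 1/2 is
#' g(0.5) + M/2 = (1 - d + M)/2 > 1/2, so the curve enters the lock-in
#' region immediately to the right of 1/2. A corollary independent of d:
#' M > 1/2 alone guarantees lock-in proneness (since M + d <= 1 forces
#' d < 1/2 < M).
#'
#' @param M Marginal majority effect.
#' @param d Inherent appeal difference.
#' @return A list of class `criterion_report` with `M`, `d`, `feasible`,
#'   `mm_condition` (M > d), `corollary` (M > 0.5), and `lock_in_guaranteed`.
#' @examples
#' mm_criterion(0.2, 0.1)
#' @export
mm_criterion <- function(M, d) {
  stopifnot(is.numeric(M), is.numeric(d), length(M) == 1, length(d) == 1)
  if (!check_feasibility(M, d))
    stop("infeasible (M, d): need M >= 0, d >= 0, M + d <= 1", call. = FALSE)
  structure(list(M = M, d = d, feasible = TRUE,
                 mm_condition = M > d, corollary = M > 0.5,
                 lock_in_guaranteed = M > d),
            class = "criterion_report")
}

#' @export
print.criterion_report <- function(x, ...) {
  cat(sprintf("M = %g, d = %g: M > d is %s; lock-in %s\n", x$M, x$d,
              x$mm_condition,
              if (x$lock_in_guaranteed) "guaranteed" else "not guaranteed by M > d"))
  invisible(x)
}

#' Walk parameters of the auxiliary step process
#'
#' The lower-bounding step process (curve 0 below 1/2, (1-d)/2 at 1/2,
#' (1-d+M)/2 above) started from counts (1, 1) is, through X_n = 2 Y_n - n,
#' a unit-step Markov chain on the integers with up-step probability
#' q0 = (1-d)/2 at state 0 and q_plus = (1-d+M)/2 at positive states.
#' q_plus > 1/2 exactly when M > d.
#'
#' @inheritParams mm_criterion
#' @return A list of class `walk_params` with `q0` and `q_plus`.
#' @export
walk_params <- function(M, d) {
  if (!check_feasibility(M, d))
    stop("infeasible (M, d)", call. = FALSE)
  structure(list(q0 = (1 - d) / 2, q_plus = (1 - d + M) / 2),
            class = "walk_params")
}

#' Closed-form lower bound on the lock-in probability
#'
#' When M > d, the probability that the inherently less appealing option
#' holds the long-run majority satisfies
#' \deqn{p_L \ge \frac{2 (M - d)(1 - d)}{(1 - d)(1 - d + M) + 2 M}.}
#' The bound is the exact survival probability of the auxiliary biased walk
#' (see [walk_survival_probability()]); the two expressions agree
#' identically under the mapping of [walk_params()]. For M = 0.2, d = 0.1
#' the bound is 0.18/1.39, about 13%.
#'
#' The bound is only asserted for M > d; calling it with M <= d is an error
#' rather than a silent zero, because the underlying result is silent there.
#'
#' @inheritParams mm_criterion
#' @return A list of class `bound_report` with `p_L_lower`, `never_return_p1`
#'   (probability the walk never returns to 0 from state 1), `q0`, `q_plus`,
#'   `M`, `d`.
#' @examples
#' lock_in_probability_bound(0.2, 0.1)$p_L_lower  # 0.18/1.39 = 0.1295
#' @export
lock_in_probability_bound <- function(M, d) {
  if (!check_feasibility(M, d))
    stop("infeasible (M, d)", call. = FALSE)
  if (M <= d)
    stop("bound requires M > d; nothing is asserted for M <= d", call. = FALSE)
  p <- 2 * (M - d) * (1 - d) / ((1 - d) * (1 - d + M) + 2 * M)
  wp <- walk_params(M, d)
  structure(list(p_L_lower = p,
                 never_return_p1 = (2 * wp$q_plus - 1) / wp$q_plus,
                 q0 = wp$q0, q_plus = wp$q_plus, M = M, d = d),
            class = "bound_report")
}

#' @export
print.bound_report <- function(x, ...) {
  cat(sprintf("lock-in probability >= %.6g  (M = %g, d = %g; q0 = %g, q+ = %g)\n",
              x$p_L_lower, x$M, x$d, x$q0, x$q_plus))
  invisible(x)
}

#' Survival probability of a biased walk with a boundary state
#'
#' For a unit-step Markov chain on the integers with up-step probability
#' `q0` at state 0 and `q_plus` > 1/2 at all positive states, the
#' probability of never going below 0 when started at 0 is
#' \deqn{\frac{q_0 (2 q_+ - 1)}{q_+ - q_0 (1 - q_+)}.}
#'
#' @param params A [walk_params] object, or a numeric `q0` with `q_plus`
#'   supplied separately.
#' @param q_plus Up-step probability at positive states (ignored when
#'   `params` is a `walk_params`).
#' @return A list with `survival` and `p1` (probability of never returning
#'   to 0 from state 1, (2 q_+ - 1)/q_+).
#' @examples
#' walk_survival_probability(0.45, 0.55)$survival  # 0.1295
#' @export
walk_survival_probability <- function(params, q_plus = NULL) {
  if (inherits(params, "walk_params")) {
    q0 <- params$q0; qp <- params$q_plus
  } else {
    q0 <- params; qp <- q_plus
  }
  stopifnot(is.numeric(q0), is.numeric(qp))
  if (q0 < 0 || q0 > 1) stop("q0 must lie in [0, 1]", call. = FALSE)
  if (qp <= 0.5) stop("q_plus must exceed 1/2", call. = FALSE)
  list(survival = q0 * (2 * qp - 1) / (qp - q0 * (1 - qp)),
       p1 = (2 * qp - 1) / qp)
}

#' Probability of observing no lock-in in k independent trials
#'
#' With per-trial lock-in probability at least p_L, the probability of zero
#' lock-ins across k independent trials is at most (1 - p_L)^k, which serves
#' as a p-value for the absence of lock-in.
#'
#' @param p_L Per-trial lock-in probability.
#' @param k Number of trials.
#' @return (1 - p_L)^k.
#' @examples
#' zero_lock_in_probability(0.3, 10)  # about 0.028
#' @export
zero_lock_in_probability <- function(p_L, k) {
  stopifnot(is.numeric(p_L), is.numeric(k))
  if (any(p_L < 0 | p_L > 1)) stop("p_L must lie in [0, 1]", call. = FALSE)
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  (1 - p_L)^k
}

#' Monte-Carlo estimate of walk survival
#'
#' Brute-force oracle for [walk_survival_probability()]: simulates `reps`
#' walks for `horizon` steps and reports the fraction that never went below
#' 0. The event "survives forever" is truncated at the horizon; with
#' q_plus > 1/2 the truncation bias is exponentially small in the horizon.
#'
#' @inheritParams walk_survival_probability
#' @param horizon Steps per walk (>= 1000).
#' @param reps Number of walks (>= 1000).
#' @param seed Optional integer seed.
#' @return A list with `estimate`, `se` (binomial Monte-Carlo standard
#'   error), `reps`, `horizon`.
#' @export
mc_walk_survival <- function(params, q_plus = NULL, horizon = 1e4,
                             reps = 1e5, seed = NULL) {
  if (inherits(params, "walk_params")) {
    q0 <- params$q0; qp <- params$q_plus
  } else {
    q0 <- params; qp <- q_plus
  }
  stopifnot(is.numeric(q0), is.numeric(qp), q0 >= 0, q0 <= 1,
            qp >= 0, qp <= 1)
  if (horizon < 1000 || reps < 1000)
    stop("horizon and reps must each be >= 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  surv <- cpp_walk_survival(q0, qp, as.integer(horizon), as.integer(reps))
  est <- surv / reps
  list(estimate = est, se = sqrt(est * (1 - est) / reps),
       reps = as.integer(reps), horizon = as.integer(horizon))
}
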