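#' Specification of a sequential binary choice process
#'
#' A generalized urn: participants arrive one at a time; participant t sees
#' the current popularity x_t = (init_a + prior A choices) / (init_a + init_b
#' + t - 1) and chooses A with probability f(x_t). The initial counts act as
#' artificial prior choices (seeding); the default (1, 1) makes the first
#' participant see popularity 1/2 and makes the auxiliary step process
#' coincide exactly with the biased-walk construction behind the lock-in
#' probability bound.
#'
#' @param curve An [influence_curve].
#' @param horizon Number of participants (>= 1).
#' @param init_a,init_b Nonnegative initial counts, summing to >= 1.
#' @return A `process_spec` object.
#' @export
process_spec <- function(curve, horizon, init_a = 1, init_b = 1) {
  stopifnot(inherits(curve, "influence_curve"))
  if (!(is.numeric(horizon) && length(horizon) == 1 && horizon >= 1))
    stop("horizon must be a count >= 1", call. = FALSE)
  if (init_a < 0 || init_b < 0 || init_a + init_b < 1)
    stop("init counts must be >= 0 with init_a + init_b >= 1", call. = FALSE)
  structure(list(curve = curve, horizon = as.integer(horizon),
                 init_a = init_a, init_b = init_b),
            class = "process_spec")
}

#' Simulate one trial of the choice process
#'
#' @param spec A [process_spec].
#' @param seed Optional integer seed (set before drawing; identical seeds give
#'   identical trajectories).
#' @return A list of class `trajectory` with `choice` (character "A"/"B"),
#'   `x` (popularity seen by each participant), `end_popularity`, and
#'   `survived` (popularity never dropped below 1/2, including at the end).
#' @export
simulate_trial <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "process_spec"))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate_trial(curve_to_cspec(spec$curve), spec$init_a,
                            spec$init_b, spec$horizon)
  structure(list(choice = ifelse(res$choice == 1L, "A", "B"),
                 x = res$x, end_popularity = res$end_popularity,
                 survived = res$survived, spec = spec),
            class = "trajectory")
}

#' Simulate an ensemble of independent trials (multiple worlds)
#'
#' Runs `n_trials` independent replicates of the same choice process, as in a
#' multiple-world experiment, and summarizes end-of-trial popularities.
#' Lock-in is counted when the end popularity of option A strictly exceeds
#' 1/2.
#'
#' @param spec A [process_spec].
#' @param n_trials Number of independent trials (>= 1).
#' @param seed Optional integer master seed; the whole ensemble is drawn from
#'   one stream, so the same seed reproduces the ensemble exactly.
#' @return A list of class `ensemble_result` with `end_popularity`,
#'   `survived`, `lock_in_count`, `lock_in_flag`, and `n_trials`.
#' @export
simulate_ensemble <- function(spec, n_trials, seed = NULL) {
  stopifnot(inherits(spec, "process_spec"))
  if (!(is.numeric(n_trials) && length(n_trials) == 1 && n_trials >= 1))
    stop("n_trials must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate_ensemble(curve_to_cspec(spec$curve), spec$init_a,
                               spec$init_b, spec$horizon, as.integer(n_trials))
  li <- end_of_trial_lock_in(res$end_popularity, threshold = 0.5)
  structure(list(end_popularity = res$end_popularity,
                 survived = res$survived,
                 lock_in_count = li$count, lock_in_flag = li$flag,
                 n_trials = as.integer(n_trials), spec = spec),
            class = "ensemble_result")
}

#' End-of-trial lock-in detection
#'
#' An item exhibits lock-in when the inherently less appealing option holds
#' an end-of-trial majority in at least one trial. The inequality is strict:
#' an exact tie is not lock-in. For the party-signal variant pass the
#' end-of-trial support differences and `threshold = 0`.
#'
#' @param end_values Numeric vector of end-of-trial popularities (or support
#'   differences).
#' @param threshold Lock-in threshold: 0.5 for popularities, 0 for party
#'   support differences.
#' @return List with `flag` (any trial locked in) and `count`.
#' @export
end_of_trial_lock_in <- function(end_values, threshold = 0.5) {
  if (length(end_values) < 1) stop("empty ensemble", call. = FALSE)
  stopifnot(is.numeric(end_values))
  cnt <- sum(end_values > threshold)
  list(flag = cnt >= 1, count = cnt)
}

#' Specification of the party-signal choice process
#'
#' Variant in which each participant belongs to one of two groups (parties A
#' and B) and sees only the sign of x = x_A - x_B, the difference in current
#' support shares for a statement between the two parties. A party-P
#' participant supports the statement with probability `p_plus_P` when
#' party-A support leads (x > 0) and `p_minus_P` when it trails (x < 0);
#' when x = 0 or undefined (either party has no prior participants) the mean
#' of the two probabilities applies, mirroring the convention that the jump
#' part of an influence curve vanishes at the tie point.
#'
#' @param p_plus_a,p_minus_a,p_plus_b,p_minus_b Support probabilities in
#'   \[0, 1\].
#' @param horizon Number of participants.
#' @param assignment Party assignment rule: "alternating" (A, B, A, B, ...)
#'   or "random" (fair coin per participant).
#' @return A `party_spec` object.
#' @export
party_spec <- function(p_plus_a, p_minus_a, p_plus_b, p_minus_b, horizon,
                       assignment = c("alternating", "random")) {
  probs <- c(p_plus_a, p_minus_a, p_plus_b, p_minus_b)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("support probabilities must lie in [0, 1]", call. = FALSE)
  if (!(is.numeric(horizon) && horizon >= 2))
    stop("horizon must be >= 2", call. = FALSE)
  assignment <- match.arg(assignment)
  structure(list(p_plus_a = p_plus_a, p_minus_a = p_minus_a,
                 p_plus_b = p_plus_b, p_minus_b = p_minus_b,
                 horizon = as.integer(horizon), assignment = assignment),
            class = "party_spec")
}

#' Map (M, d) to party-signal support probabilities
#'
#' Constructs the symmetric party-signal process whose party-level influence
#' curves are flat on either side of x = 0 with per-party jumps M_A = M,
#' M_B = -M (so the combined marginal majority effect (M_A - M_B)/2 equals M)
#' and tie-point support probabilities (1-d)/2 for party A and (1+d)/2 for
#' party B (so the ideological content, the control-condition support gap, is
#' d).
#'
#' @param M Marginal majority effect in \[0, 1\].
#' @param d Inherent appeal (ideological content) difference.
#' @inheritParams party_spec
#' @return A `party_spec`.
#' @export
party_spec_from_md <- function(M, d, horizon,
                               assignment = c("alternating", "random")) {
  if (!check_feasibility(M, d))
    stop("(M, d) infeasible: need M, d >= 0 and M + d <= 1", call. = FALSE)
  party_spec(p_plus_a = (1 - d + M) / 2, p_minus_a = (1 - d - M) / 2,
             p_plus_b = (1 + d - M) / 2, p_minus_b = (1 + d + M) / 2,
             horizon = horizon, assignment = match.arg(assignment))
}

#' Simulate one trial of the party-signal process
#'
#' @param spec A [party_spec].
#' @param seed Optional integer seed.
#' @return A list of class `party_trajectory` with `party` ("A"/"B" per
#'   record), `support` (0/1), `x` (signal seen; `NA` while undefined),
#'   `ybar_a`, `ybar_b` (end-of-trial support shares) and `ybar` = ybar_a -
#'   ybar_b.
#' @export
simulate_party_trial <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "party_spec"))
  if (!is.null(seed)) set.seed(seed)
  party <- if (spec$assignment == "alternating") {
    rep_len(c(0L, 1L), spec$horizon)
  } else {
    sample(c(0L, 1L), spec$horizon, replace = TRUE)
  }
  res <- cpp_simulate_party(spec$p_plus_a, spec$p_minus_a,
                            spec$p_plus_b, spec$p_minus_b, party)
  structure(list(party = ifelse(party == 0L, "A", "B"),
                 support = res$support, x = res$x,
                 ybar_a = res$ybar_a, ybar_b = res$ybar_b,
                 ybar = res$ybar_a - res$ybar_b, spec = spec),
            class = "party_trajectory")
}

#' Simulate an ensemble of party-signal trials
#'
#' @inheritParams simulate_party_trial
#' @param n_trials Number of independent trials.
#' @return List of class `party_ensemble` with `ybar` (end-of-trial support
#'   differences), `lock_in_count` (trials with ybar > 0) and `lock_in_flag`.
#' @export
simulate_party_ensemble <- function(spec, n_trials, seed = NULL) {
  stopifnot(inherits(spec, "party_spec"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  ybar <- vapply(seq_len(n_trials),
                 function(i) simulate_party_trial(spec)$ybar, numeric(1))
  li <- end_of_trial_lock_in(ybar, threshold = 0)
  structure(list(ybar = ybar, lock_in_count = li$count,
                 lock_in_flag = li$flag, n_trials = as.integer(n_trials),
                 spec = spec),
            class = "party_ensemble")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result: %d trials, horizon %d, lock-in %d (%.1f%%)>\n",
    x$n_trials, x$spec$horizon, x$lock_in_count,
    100 * x$lock_in_count / x$n_trials))
  invisible(x)
}
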