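#' Design of a synthetic multiple-world experiment
#'
#' Describes an experiment to be emulated: a number of items (questions),
#' each run in several independent worlds (trials) of sequential
#' participants, plus a control sample per item with no social influence.
#' Ground-truth behavior per item is a step influence curve drawn from the
#' given (M, d) ranges: value (1-d-M)/2 below popularity 1/2, (1-d)/2 at
#' 1/2, and (1-d+M)/2 above. World structure is given in blocks, each block
#' contributing a number of worlds (fixed or drawn from a range) of a given
#' length and initial artificial counts.
#'
#' @param n_items Number of items.
#' @param blocks List of world blocks; each block is a list with `n_worlds`
#'   (a count, or a length-2 range sampled per item), `participants` (world
#'   length), and optionally `init_a`, `init_b` (artificial initial counts,
#'   default 0 each).
#' @param control_n Control-condition sample size per item (default 200,
#'   which puts the standard error of the appeal-difference estimate near
#'   0.035).
#' @param M_range,d_range Ranges for the per-item marginal majority effect
#'   and inherent appeal difference; `max(M_range) + max(d_range)` must not
#'   exceed 1.
#' @param party Use the party-signal design (sign-only popularity signal,
#'   alternating party assignment) instead of the standard design?
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(n_items, blocks, control_n = 200,
                              M_range = c(0, 0.4), d_range = c(0, 0.4),
                              party = FALSE) {
  stopifnot(n_items >= 1, is.list(blocks), length(blocks) >= 1,
            control_n >= 1)
  if (max(M_range) + max(d_range) > 1)
    stop("infeasible ranges: max(M) + max(d) must be <= 1", call. = FALSE)
  for (b in blocks) {
    if (is.null(b$n_worlds) || is.null(b$participants))
      stop("each block needs n_worlds and participants", call. = FALSE)
  }
  structure(list(n_items = as.integer(n_items), blocks = blocks,
                 control_n = as.integer(control_n),
                 M_range = M_range, d_range = d_range, party = party),
            class = "experiment_design")
}

#' Published multiple-world designs
#'
#' Preset [experiment_design()]s mirroring the three reanalyzed study
#' layouts: a taste-judgment study with 7 items and 2 worlds each (about 530
#' and 3500 participants, the long world giving the less appealing option an
#' artificial initial advantage of about 110 to 10); a party-signal study
#' with 20 statements in 8 worlds of 230 participants; and a trivia study
#' with 30 items in 10-15 worlds of 100 participants plus 20-30 worlds of 15
#' participants. Ground-truth (M, d) ranges reflect the regimes those
#' studies exhibited: small-to-moderate M with moderate-to-large d (no
#' lock-in), large M with small d (lock-in throughout), and broad ranges of
#' both (mixed).
#'
#' @name design_presets
#' @return An `experiment_design`.
NULL

#' @rdname design_presets
#' @export
design_v2019 <- function() {
  experiment_design(
    n_items = 7,
    blocks = list(
      list(n_worlds = 1, participants = 530),
      list(n_worlds = 1, participants = 3500, init_a = 110, init_b = 10)),
    control_n = 200,
    M_range = c(0, 0.17), d_range = c(0.2, 0.6))
}

#' @rdname design_presets
#' @export
design_mdrt2019 <- function() {
  experiment_design(
    n_items = 20,
    blocks = list(list(n_worlds = 8, participants = 230)),
    control_n = 200,
    M_range = c(0.065, 0.35), d_range = c(0, 0.15),
    party = TRUE)
}

#' @rdname design_presets
#' @export
design_fv2021 <- function() {
  experiment_design(
    n_items = 30,
    blocks = list(
      list(n_worlds = c(10, 15), participants = 100),
      list(n_worlds = c(20, 30), participants = 15)),
    control_n = 200,
    M_range = c(0, 0.4), d_range = c(0, 0.5))
}

draw_n_worlds <- function(spec) {
  if (length(spec) == 1) return(as.integer(spec))
  as.integer(sample(seq(spec[1], spec[2]), 1))
}

#' Generate a synthetic multiple-world experiment
#'
#' Draws per-item ground truth (M, d) uniformly from the design's ranges
#' (resampling any pair with M + d > 1), simulates every social world with
#' the generalized-urn simulator under the item's step influence curve, and
#' draws the control sample as independent Bernoulli choices with
#' P(A) = g(0.5) = (1-d)/2 (so the appeal-difference estimator targets
#' d = 1 - 2 g(0.5)). In party mode, worlds follow the sign-only
#' party-signal process with alternating party assignment and the control
#' sample draws party-A members with support probability (1-d)/2 and
#' party-B members with (1+d)/2; support is recorded as choice "A".
#'
#' @param design An [experiment_design()].
#' @param seed Integer master seed; the whole fixture is drawn from one
#'   stream, so identical seeds give identical fixtures.
#' @return A list of class `experiment_fixture` with `table` (a
#'   [choice_table]), `truth` (per-item data frame: `item_id`, `M`, `d`,
#'   `low`, `mid`, `high`, `mm_condition`, `p_L_lower`), and `design`.
#' @export
generate_experiment <- function(design, seed = 1) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(seed)
  recs <- list(); inits <- list(); truths <- list()
  for (i in seq_len(design$n_items)) {
    item <- sprintf("item%02d", i)
    repeat {
      M <- stats::runif(1, design$M_range[1], design$M_range[2])
      d <- stats::runif(1, design$d_range[1], design$d_range[2])
      if (M + d <= 1) break
    }
    low <- (1 - d - M) / 2; mid <- (1 - d) / 2; high <- (1 - d + M) / 2
    truths[[i]] <- data.frame(
      item_id = item, M = M, d = d, low = low, mid = mid, high = high,
      mm_condition = M > d,
      p_L_lower = if (M > d) lock_in_probability_bound(M, d)$p_L_lower
                  else NA_real_,
      stringsAsFactors = FALSE)
    w_idx <- 0
    for (b in design$blocks) {
      nw <- draw_n_worlds(b$n_worlds)
      ia <- if (is.null(b$init_a)) 0 else b$init_a
      ib <- if (is.null(b$init_b)) 0 else b$init_b
      for (w in seq_len(nw)) {
        w_idx <- w_idx + 1
        world <- sprintf("w%02d", w_idx)
        np <- b$participants
        if (design$party) {
          ps <- party_spec_from_md(M, d, horizon = np,
                                   assignment = "alternating")
          tr <- simulate_party_trial(ps)
          recs[[length(recs) + 1]] <- data.frame(
            item_id = item, world_id = world, t = seq_len(np),
            choice = ifelse(tr$support == 1, "A", "B"),
            condition = "social", party = tr$party,
            stringsAsFactors = FALSE)
        } else {
          crv <- step_curve(low, high, mid)
          tr <- cpp_simulate_trial(curve_to_cspec(crv), ia, ib, np)
          recs[[length(recs) + 1]] <- data.frame(
            item_id = item, world_id = world, t = seq_len(np),
            choice = ifelse(tr$choice == 1L, "A", "B"),
            condition = "social",
            stringsAsFactors = FALSE)
          if (ia > 0 || ib > 0) {
            inits[[length(inits) + 1]] <- data.frame(
              item_id = item, world_id = world, init_a = ia, init_b = ib,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    nc <- design$control_n
    if (design$party) {
      party <- rep_len(c("A", "B"), nc)
      p <- ifelse(party == "A", (1 - d) / 2, (1 + d) / 2)
      supp <- stats::rbinom(nc, 1, p)
      recs[[length(recs) + 1]] <- data.frame(
        item_id = item, world_id = "control", t = seq_len(nc),
        choice = ifelse(supp == 1, "A", "B"),
        condition = "control", party = party, stringsAsFactors = FALSE)
    } else {
      ch <- stats::rbinom(nc, 1, mid)
      recs[[length(recs) + 1]] <- data.frame(
        item_id = item, world_id = "control", t = seq_len(nc),
        choice = ifelse(ch == 1, "A", "B"),
        condition = "control", stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  if (design$party && is.null(records$party)) records$party <- NA_character_
  init <- if (length(inits) > 0) do.call(rbind, inits) else NULL
  structure(list(table = choice_table(records, init),
                 truth = do.call(rbind, truths), design = design,
                 seed = seed),
            class = "experiment_fixture")
}

#' @export
print.experiment_fixture <- function(x, ...) {
  cat(sprintf("<experiment_fixture: %d items, %d records, seed %d>\n",
              x$design$n_items, nrow(x$table$records), x$seed))
  invisible(x)
}
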