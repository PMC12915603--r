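#' Long-format table of sequential choices
#'
#' The record format for multiple-world experiments: one row per participant
#' with the experimental item, the world (independent trial) the participant
#' was in, the 1-based arrival index `t` within that world, the chosen
#' option, the condition (`"social"`: saw popularity information;
#' `"control"`: did not), and an optional party label for the party-signal
#' design. Per-world artificial initial counts (seeding) live in a separate
#' `init` table so the records stay strictly long-format.
#'
#' @param records Data frame with columns `item_id`, `world_id`, `t`,
#'   `choice` (values "A"/"B"), `condition` ("social"/"control") and
#'   optionally `party` ("A"/"B").
#' @param init Data frame with columns `item_id`, `world_id`, `init_a`,
#'   `init_b`; worlds absent from it default to counts (0, 0).
#' @return An object of class `choice_table`.
#' @export
choice_table <- function(records, init = NULL) {
  req <- c("item_id", "world_id", "t", "choice", "condition")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    stop("records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(records$choice %in% c("A", "B")))
    stop("choice must be 'A' or 'B'", call. = FALSE)
  if (!all(records$condition %in% c("social", "control")))
    stop("condition must be 'social' or 'control'", call. = FALSE)
  key <- interaction(records$item_id, records$world_id, records$condition,
                     drop = TRUE)
  for (k in levels(key)) {
    tt <- sort(records$t[key == k])
    if (!identical(as.integer(tt), seq_along(tt)))
      stop("participant index t not contiguous from 1 in (item, world) ",
           sub("\\.", ", ", k), call. = FALSE)
  }
  if (is.null(init)) {
    init <- data.frame(item_id = character(0), world_id = character(0),
                       init_a = numeric(0), init_b = numeric(0))
  }
  structure(list(records = records, init = init), class = "choice_table")
}

#' @export
print.choice_table <- function(x, ...) {
  cat(sprintf("<choice_table: %d records, %d items, %d worlds>\n",
              nrow(x$records), length(unique(x$records$item_id)),
              nrow(unique(x$records[, c("item_id", "world_id")]))))
  invisible(x)
}

init_counts_for <- function(ct, item, world) {
  i <- which(ct$init$item_id == item & ct$init$world_id == world)
  if (length(i) == 0) c(init_a = 0, init_b = 0)
  else c(init_a = ct$init$init_a[i[1]], init_b = ct$init$init_b[i[1]])
}

#' Attach the running popularity of option A to each record
#'
#' For participant t in a world, x_t = (init_a + number of prior A choices)
#' / (init_a + init_b + t - 1): the proportion of previous participants
#' (including any artificial initial counts) that chose A at the moment of
#' the choice. Records whose denominator is zero (first participant of an
#' unseeded world) get `x = NA` and are excluded from curve estimation
#' downstream.
#'
#' @param ct A [choice_table] (or its `records` data frame plus `init`).
#' @param option_a Which stored label plays the role of option A (curves and
#'   popularities are computed for this option). Default "A".
#' @return The records data frame with an added numeric column `x`.
#' @export
attach_running_popularity <- function(ct, option_a = "A") {
  stopifnot(inherits(ct, "choice_table"))
  rec <- ct$records
  rec$x <- NA_real_
  key <- interaction(rec$item_id, rec$world_id, rec$condition, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    idx <- idx[order(rec$t[idx])]
    first <- idx[1]
    ini <- init_counts_for(ct, rec$item_id[first], rec$world_id[first])
    ia <- ini["init_a"]; ib <- ini["init_b"]
    if (option_a != "A") { tmp <- ia; ia <- ib; ib <- tmp }
    isA <- as.numeric(rec$choice[idx] == option_a)
    priorA <- ia + c(0, cumsum(isA))[seq_along(idx)]
    denom <- ia + ib + (rec$t[idx] - 1)
    x <- ifelse(denom > 0, priorA / denom, NA_real_)
    rec$x[idx] <- x
  }
  rec
}

#' Binned empirical influence curve
#'
#' Pools records from all worlds and groups them by the current popularity x
#' of option A in bins of width `bin_width` (default 0.1). The per-bin
#' estimate is the weighted share of participants choosing A. Records whose
#' x falls exactly on an interior bin edge contribute weight one-half to
#' each adjacent bin; records at x = 0.5 are excluded by default, since the
#' marginal majority effect is defined without the tie point.
#'
#' @param records Data frame with columns `x` and `choice` (e.g. from
#'   [attach_running_popularity()]); rows with `NA` x are dropped.
#' @param bin_width Bin width; 1/bin_width must be an integer and 0.5 must
#'   be a bin edge.
#' @param exclude_half Drop records at exactly x = 0.5 (default `TRUE`).
#' @param option_a Label counted as option A.
#' @return A list of class `binned_curve` with a `bins` data frame (`lower`,
#'   `upper`, `n_eff`, `estimate`, `se`) and the settings used. Empty bins
#'   have `n_eff = 0` and `NA` estimates.
#' @export
bin_influence_curve <- function(records, bin_width = 0.1,
                                exclude_half = TRUE, option_a = "A") {
  stopifnot(is.data.frame(records), all(c("x", "choice") %in% names(records)))
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9)
    stop("1/bin_width must be an integer", call. = FALSE)
  if (nb %% 2 != 0)
    stop("0.5 must be a bin edge (even number of bins)", call. = FALSE)
  rec <- records[!is.na(records$x), , drop = FALSE]
  if (nrow(rec) == 0) stop("no records with defined popularity", call. = FALSE)
  x <- rec$x
  a <- as.numeric(rec$choice == option_a)
  if (exclude_half) {
    keep <- abs(x - 0.5) > 1e-12
    x <- x[keep]; a <- a[keep]
  }
  if (length(x) == 0) stop("no usable records after exclusions", call. = FALSE)
  w <- numeric(nb); wa <- numeric(nb)
  pos <- x / bin_width
  on_edge <- abs(pos - round(pos)) < 1e-9 & round(pos) > 0 & round(pos) < nb
  # interior-edge records: half weight in each adjacent bin
  if (any(on_edge)) {
    j <- round(pos[on_edge])
    for (i in seq_along(j)) {
      w[j[i]] <- w[j[i]] + 0.5
      w[j[i] + 1] <- w[j[i] + 1] + 0.5
      wa[j[i]] <- wa[j[i]] + 0.5 * a[on_edge][i]
      wa[j[i] + 1] <- wa[j[i] + 1] + 0.5 * a[on_edge][i]
    }
  }
  if (any(!on_edge)) {
    j <- pmin(pmax(floor(pos[!on_edge] + 1e-12), 0), nb - 1) + 1
    for (i in seq_along(j)) {
      w[j[i]] <- w[j[i]] + 1
      wa[j[i]] <- wa[j[i]] + a[!on_edge][i]
    }
  }
  est <- ifelse(w > 0, wa / w, NA_real_)
  se <- ifelse(w > 0, sqrt(pmax(est * (1 - est), 0) / w), NA_real_)
  bins <- data.frame(lower = (seq_len(nb) - 1) * bin_width,
                     upper = seq_len(nb) * bin_width,
                     n_eff = w, estimate = est, se = se)
  structure(list(bins = bins, bin_width = bin_width,
                 exclude_half = exclude_half, n_records = length(x)),
            class = "binned_curve")
}

#' @export
print.binned_curve <- function(x, ...) {
  cat(sprintf("<binned_curve: width %g, %g effective records>\n",
              x$bin_width, sum(x$bins$n_eff)))
  print(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Convert a binned estimate to a piecewise-constant influence curve
#'
#' Empty bins are filled by carrying the nearest estimated value (needed only
#' to produce a complete curve object); the result is rejected if the filled
#' values are decreasing.
#'
#' @param binned A `binned_curve`.
#' @return An [influence_curve] of kind piecewise_constant.
#' @export
as_influence_curve <- function(binned) {
  stopifnot(inherits(binned, "binned_curve"))
  v <- binned$bins$estimate
  if (all(is.na(v))) stop("no estimated bins", call. = FALSE)
  # fill NAs from the nearest non-NA neighbour (ties: from the left)
  idx <- which(!is.na(v))
  v <- v[idx][pmax(1, findInterval(seq_along(v), idx))]
  piecewise_curve(c(binned$bins$lower, 1), v)
}

#' Estimate the marginal majority effect from a binned curve
#'
#' M is the increase of the empirical influence curve between the two
#' central bins, (0.4, 0.5) and (0.5, 0.6) at the default width: the
#' discontinuous gain in choice probability as the option becomes marginally
#' more popular than its rival. The standard error combines the two binomial
#' bin standard errors in quadrature.
#'
#' @param binned A `binned_curve` whose bin edges include 0.5.
#' @return A list with `M`, `se`, `n_below`, `n_above`. Raises an error when
#'   either central bin is empty (no data to estimate M).
#' @export
estimate_M <- function(binned) {
  stopifnot(inherits(binned, "binned_curve"))
  b <- binned$bins
  below <- which(abs(b$upper - 0.5) < 1e-9)
  above <- which(abs(b$lower - 0.5) < 1e-9)
  if (length(below) != 1 || length(above) != 1)
    stop("bin edges must include 0.5", call. = FALSE)
  if (b$n_eff[below] == 0 || b$n_eff[above] == 0)
    stop("no data to estimate M: a central bin is empty", call. = FALSE)
  list(M = b$estimate[above] - b$estimate[below],
       se = sqrt(b$se[above]^2 + b$se[below]^2),
       n_below = b$n_eff[below], n_above = b$n_eff[above])
}

#' Identify option A and estimate the inherent appeal difference
#'
#' Option A is the inherently less appealing option, operationalized as the
#' option chosen less often in the control condition (no social influence).
#' The appeal difference is d = p_B - p_A, the control-condition gap in
#' choice probability, which is nonnegative by construction. An exact 50/50
#' control splits ties lexicographically (the smaller label becomes A) and
#' is flagged.
#'
#' @param choices Character vector of control-condition choices (exactly two
#'   distinct labels expected; a single observed label means the other was
#'   never chosen).
#' @param labels Optional length-2 character vector fixing the candidate
#'   labels (needed when only one label occurs).
#' @return A list with `option_a`, `option_b`, `d`, `se`, `n`, `tie`.
#' @export
estimate_d_and_option_a <- function(choices, labels = NULL) {
  if (length(choices) == 0) stop("empty control set", call. = FALSE)
  if (is.null(labels)) labels <- sort(unique(as.character(choices)))
  if (length(labels) == 1) labels <- sort(c(labels, setdiff(c("A", "B"), labels)))
  if (length(labels) != 2) stop("expected exactly two option labels", call. = FALSE)
  labels <- sort(labels)
  n <- length(choices)
  n1 <- sum(choices == labels[1])
  n2 <- n - n1
  tie <- n1 == n2
  if (n1 <= n2) { a <- labels[1]; pa <- n1 / n } else { a <- labels[2]; pa <- n2 / n }
  list(option_a = a, option_b = setdiff(labels, a), d = 1 - 2 * pa,
       se = 2 * sqrt(pa * (1 - pa) / n), n = n, tie = tie)
}

#' Attach the party-signal x to each record
#'
#' For the party-signal design: each record's signal is x = x_A - x_B, the
#' difference between the support shares of the statement among prior
#' same-world participants of party A and of party B. The signal is `NA`
#' until both parties have at least one prior participant in the world.
#'
#' @param ct A [choice_table] whose records carry a `party` column; `choice`
#'   "A" is read as supporting the statement.
#' @return The records data frame with an added column `x`.
#' @export
attach_party_signal <- function(ct) {
  stopifnot(inherits(ct, "choice_table"))
  rec <- ct$records
  if (is.null(rec$party)) stop("records lack a party column", call. = FALSE)
  rec$x <- NA_real_
  key <- interaction(rec$item_id, rec$world_id, rec$condition, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    idx <- idx[order(rec$t[idx])]
    nA <- sA <- nB <- sB <- 0
    for (i in idx) {
      if (nA > 0 && nB > 0) rec$x[i] <- sA / nA - sB / nB
      s <- as.numeric(rec$choice[i] == "A")
      if (rec$party[i] == "A") { nA <- nA + 1; sA <- sA + s }
      else { nB <- nB + 1; sB <- sB + s }
    }
  }
  rec
}

#' Party-signal estimates of M and d
#'
#' Social records are grouped by the sign of the party-signal x (records
#' with x = 0 or undefined are ignored). Within each group the influence
#' value is y = y_A - y_B, the support-share difference between parties.
#' Per-party marginal majority effects are M_P = y_P(x > 0) - y_P(x < 0),
#' and the combined effect is M = (M_A - M_B)/2, scaled so that it lies in
#' \[0, 1\] under the model. The ideological content is estimated from the
#' control condition as d = p_B - p_A, the gap in support probability
#' between the two parties' members.
#'
#' @param ct A [choice_table] with a `party` column; social records are used
#'   for M, control records for d.
#' @return A list of class `party_estimate` with `M`, `M_se`, `M_a`, `M_b`,
#'   `d`, `d_se`, `y_plus`, `y_minus` (the two-sided influence values),
#'   `n_plus`, `n_minus`.
#' @export
party_estimates <- function(ct) {
  rec <- attach_party_signal(ct)
  soc <- rec[rec$condition == "social" & !is.na(rec$x) & rec$x != 0, ,
             drop = FALSE]
  if (nrow(soc) == 0) stop("no social records with nonzero signal", call. = FALSE)
  grp <- ifelse(soc$x > 0, "plus", "minus")
  if (!all(c("plus", "minus") %in% grp))
    stop("a sign group is empty; cannot estimate M", call. = FALSE)
  share <- function(sel) {
    if (!any(sel)) return(c(y = NA_real_, v = NA_real_, n = 0))
    p <- mean(soc$choice[sel] == "A")
    c(y = p, v = p * (1 - p) / sum(sel), n = sum(sel))
  }
  yAp <- share(grp == "plus" & soc$party == "A")
  yAm <- share(grp == "minus" & soc$party == "A")
  yBp <- share(grp == "plus" & soc$party == "B")
  yBm <- share(grp == "minus" & soc$party == "B")
  if (any(is.na(c(yAp["y"], yAm["y"], yBp["y"], yBm["y"]))))
    stop("a party/sign cell is empty; cannot estimate M", call. = FALSE)
  M_a <- unname(yAp["y"] - yAm["y"])
  M_b <- unname(yBp["y"] - yBm["y"])
  M <- (M_a - M_b) / 2
  M_se <- sqrt(sum(c(yAp["v"], yAm["v"], yBp["v"], yBm["v"]))) / 2
  ctl <- ct$records[ct$records$condition == "control", , drop = FALSE]
  if (nrow(ctl) == 0) stop("no control records to estimate d", call. = FALSE)
  pA <- mean(ctl$choice[ctl$party == "A"] == "A")
  pB <- mean(ctl$choice[ctl$party == "B"] == "A")
  nA <- sum(ctl$party == "A"); nB <- sum(ctl$party == "B")
  d <- pB - pA
  d_se <- sqrt(pA * (1 - pA) / nA + pB * (1 - pB) / nB)
  structure(list(M = M, M_se = M_se, M_a = M_a, M_b = M_b,
                 d = d, d_se = d_se,
                 y_plus = unname(yAp["y"] - yBp["y"]),
                 y_minus = unname(yAm["y"] - yBm["y"]),
                 n_plus = unname(yAp["n"] + yBp["n"]),
                 n_minus = unname(yAm["n"] + yBm["n"])),
            class = "party_estimate")
}

#' Per-item estimation pipeline
#'
#' Runs the full estimation protocol for every item of a choice table:
#' identify option A from the control condition, attach running
#' popularities, bin the influence curve, estimate M (the central-bin jump)
#' and d (the control gap), detect end-of-trial lock-in (option A holds a
#' strict majority in at least one social world), and check whether the
#' binned curve enters the lock-in region.
#'
#' @param ct A [choice_table].
#' @param bin_width Bin width for the influence curve.
#' @param min_world_length Minimum number of participants a world must have
#'   for its end-of-trial proportion to count toward lock-in detection
#'   (curve estimation always uses all worlds). Short worlds have high
#'   end-of-trial variance; designs mixing long and short worlds
#'   conventionally assess lock-in on the long ones only.
#' @return A data frame of class `item_estimates` with one row per item:
#'   `item_id`, `option_a`, `M`, `M_se`, `d`, `d_se`, `lock_in_observed`,
#'   `n_trials` (worlds counted for lock-in), `enters_lock_in_region`.
#'   Items whose central bins are empty get `NA` for M (reported, not
#'   dropped).
#' @export
estimate_items <- function(ct, bin_width = 0.1, min_world_length = 0) {
  stopifnot(inherits(ct, "choice_table"))
  items <- unique(ct$records$item_id)
  out <- lapply(items, function(it) {
    sub <- choice_table(ct$records[ct$records$item_id == it, , drop = FALSE],
                        ct$init[ct$init$item_id == it, , drop = FALSE])
    ctl <- sub$records[sub$records$condition == "control", , drop = FALSE]
    dd <- estimate_d_and_option_a(ctl$choice, labels = c("A", "B"))
    rec <- attach_running_popularity(sub, option_a = dd$option_a)
    soc <- rec[rec$condition == "social", , drop = FALSE]
    binned <- bin_influence_curve(soc, bin_width = bin_width,
                                  option_a = dd$option_a)
    Mres <- tryCatch(estimate_M(binned), error = function(e) NULL)
    # end-of-trial popularity of option A per social world (incl. init counts)
    worlds <- unique(soc$world_id)
    wlen <- vapply(worlds, function(w) sum(soc$world_id == w), numeric(1))
    worlds <- worlds[wlen >= min_world_length]
    endpop <- vapply(worlds, function(w) {
      ww <- soc[soc$world_id == w, , drop = FALSE]
      ini <- init_counts_for(sub, it, w)
      ia <- ini["init_a"]; ib <- ini["init_b"]
      if (dd$option_a != "A") { tmp <- ia; ia <- ib; ib <- tmp }
      (ia + sum(ww$choice == dd$option_a)) / (ia + ib + nrow(ww))
    }, numeric(1))
    li <- if (length(endpop) > 0) end_of_trial_lock_in(endpop, threshold = 0.5)
          else list(flag = NA, count = NA_integer_)
    elr <- tryCatch(enters_lock_in_region(binned), error = function(e) NA)
    data.frame(item_id = it, option_a = dd$option_a,
               M = if (is.null(Mres)) NA_real_ else Mres$M,
               M_se = if (is.null(Mres)) NA_real_ else Mres$se,
               d = dd$d, d_se = dd$se,
               lock_in_observed = li$flag, n_trials = length(worlds),
               enters_lock_in_region = elr,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("item_estimates", class(res))
  res
}

#' Cross-tabulate the lock-in criterion against observed lock-in
#'
#' Splits items by whether the estimated marginal majority effect exceeds
#' the estimated appeal difference (M > d) and by whether end-of-trial
#' lock-in was observed. Items without an M estimate (empty central bin) are
#' reported separately, not forced into the table.
#'
#' @param estimates A data frame with columns `M`, `d`, `lock_in_observed`
#'   (e.g. from [estimate_items()]).
#' @return A list of class `item_classification` with `table` (2x2 counts,
#'   rows `M > d` TRUE/FALSE, columns lock-in TRUE/FALSE), `no_estimate`
#'   (item count lacking M), and `items` (per-item flags).
#' @export
classify_items <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("M", "d", "lock_in_observed") %in% names(estimates)))
  if (nrow(estimates) == 0) stop("no items", call. = FALSE)
  has <- !is.na(estimates$M) & !is.na(estimates$d)
  mm <- estimates$M[has] > estimates$d[has]
  li <- estimates$lock_in_observed[has]
  tab <- matrix(c(sum(mm & li), sum(mm & !li),
                  sum(!mm & li), sum(!mm & !li)),
                nrow = 2, byrow = TRUE,
                dimnames = list(`M > d` = c("TRUE", "FALSE"),
                                `lock-in` = c("TRUE", "FALSE")))
  items <- estimates
  items$mm_condition <- NA
  items$mm_condition[has] <- mm
  structure(list(table = tab, no_estimate = sum(!has), items = items),
            class = "item_classification")
}

#' @export
print.item_classification <- function(x, ...) {
  cat("items by lock-in criterion vs observed lock-in\n")
  print(x$table)
  if (x$no_estimate > 0)
    cat(x$no_estimate, "item(s) without an M estimate\n")
  invisible(x)
}
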