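#' Influence curves for sequential binary choice
#'
#' An influence curve (urn function) maps the current popularity x of option A
#' (the share of prior participants who chose it) to the probability that the
#' next participant chooses A. Curves are nondecreasing, take values in
#' \[0, 1\], and may have a single jump at x = 1/2 -- the marginal majority
#' effect. By convention A is the inherently less appealing option, so
#' f(0.5) <= 0.5 for curves describing real systems; constructors do not force
#' this, but [decompose_curve()] reports d = 1 - 2 g(0.5) which is negative
#' when the convention is violated.
#'
#' @param low,high Values of a step curve below and above x = 1/2.
#' @param mid Value exactly at x = 1/2 (default the midpoint of `low` and
#'   `high`, matching the convention that the jump part vanishes at 1/2).
#' @param d Inherent appeal difference in \[0, 1) of a logistic curve.
#' @param b Slope parameter (>= 0) of a logistic curve.
#' @param edges Strictly increasing bin edges covering \[0, 1\].
#' @param values One value per bin, nondecreasing.
#' @param p Constant choice probability.
#'
#' @details The logistic family is
#'   \deqn{f(x) = 1 / (1 + \frac{1+d}{1-d} e^{b(1-2x)}),}
#'   which satisfies f(1/2) = (1-d)/2 and is continuous, so its marginal
#'   majority effect is zero. A step curve taking values `low` below 1/2 and
#'   `high` above has jump M = high - low. Piecewise-constant curves carry
#'   empirical binned estimates; at an interior bin edge they evaluate to the
#'   mean of the two adjacent bin values so that one-sided limits exist
#'   everywhere.
#'
#' @return An object of class `influence_curve` (with a kind-specific
#'   subclass).
#' @examples
#' f <- step_curve(0.45, 0.55)
#' evaluate_curve(f, c(0.3, 0.5, 0.7))
#' decompose_curve(f)
#' @name influence_curve
NULL

new_influence_curve <- function(kind, fields, subclass) {
  crv <- c(list(kind = kind), fields)
  class(crv) <- c(subclass, "influence_curve")
  validate_influence_curve(crv)
  crv
}

#' @rdname influence_curve
#' @export
step_curve <- function(low, high, mid = (low + high) / 2) {
  stopifnot(is.numeric(low), is.numeric(high), is.numeric(mid),
            length(low) == 1, length(high) == 1, length(mid) == 1)
  low <- unname(low); high <- unname(high); mid <- unname(mid)
  if (!(low >= 0 && low <= high && high <= 1))
    stop("step_curve requires 0 <= low <= high <= 1", call. = FALSE)
  if (!(mid >= low && mid <= high))
    stop("step_curve requires low <= mid <= high", call. = FALSE)
  new_influence_curve("step", list(low = low, high = high, mid = mid),
                      "step_curve")
}

#' @rdname influence_curve
#' @export
logistic_curve <- function(d, b) {
  stopifnot(is.numeric(d), is.numeric(b), length(d) == 1, length(b) == 1)
  d <- unname(d); b <- unname(b)
  if (d < 0 || d >= 1) stop("logistic_curve requires 0 <= d < 1", call. = FALSE)
  if (b < 0) stop("logistic_curve requires b >= 0", call. = FALSE)
  new_influence_curve("logistic", list(d = d, b = b), "logistic_curve")
}

#' @rdname influence_curve
#' @export
piecewise_curve <- function(edges, values) {
  stopifnot(is.numeric(edges), is.numeric(values))
  if (length(edges) != length(values) + 1)
    stop("need one more edge than values", call. = FALSE)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing", call. = FALSE)
  if (abs(edges[1]) > 1e-12 || abs(edges[length(edges)] - 1) > 1e-12)
    stop("edges must cover [0, 1]", call. = FALSE)
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]", call. = FALSE)
  if (any(diff(values) < 0)) stop("values must be nondecreasing", call. = FALSE)
  edges[1] <- 0; edges[length(edges)] <- 1
  new_influence_curve("piecewise_constant",
                      list(edges = edges, values = values), "piecewise_curve")
}

#' @rdname influence_curve
#' @export
constant_curve <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1)
  p <- unname(p)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  new_influence_curve("constant", list(p = p), "constant_curve")
}

#' @rdname influence_curve
#' @export
identity_curve <- function() {
  new_influence_curve("identity", list(), "identity_curve")
}

#' Mixture of influence curves
#'
#' Aggregates individual-level influence curves into a population-level curve
#' as the weighted mean of the component evaluations. Averaging preserves
#' continuity, so the jump of the mixture at x = 1/2 is the weighted mean of
#' the component jumps: heterogeneity can only smooth a curve, never create a
#' marginal majority effect that no individual exhibits.
#'
#' @param curves List of `influence_curve` objects.
#' @param weights Nonnegative weights summing to 1 (within 1e-12).
#' @return An `influence_curve` of kind mixture.
#' @examples
#' m <- aggregate_curves(list(step_curve(0, 1), constant_curve(0.5)),
#'                       c(0.3, 0.7))
#' decompose_curve(m)$M  # 0.3
#' @export
aggregate_curves <- function(curves, weights) {
  if (length(curves) == 0) stop("empty curve list", call. = FALSE)
  if (length(curves) != length(weights))
    stop("curves and weights must have equal length", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1", call. = FALSE)
  ok <- vapply(curves, inherits, logical(1), "influence_curve")
  if (!all(ok)) stop("all components must be influence curves", call. = FALSE)
  if (length(curves) == 1) return(curves[[1]])
  # flatten nested mixtures
  comp <- list(); w <- numeric(0)
  for (i in seq_along(curves)) {
    ci <- curves[[i]]
    if (identical(ci$kind, "mixture")) {
      comp <- c(comp, ci$components)
      w <- c(w, weights[i] * ci$weights)
    } else {
      comp <- c(comp, list(ci))
      w <- c(w, weights[i])
    }
  }
  crv <- list(kind = "mixture", components = comp, weights = w)
  class(crv) <- c("mixture_curve", "influence_curve")
  validate_influence_curve(crv)
  crv
}

# Flatten a curve into the representation the C++ evaluator understands.
curve_to_cspec <- function(curve) {
  comps <- if (identical(curve$kind, "mixture")) curve$components else list(curve)
  w <- if (identical(curve$kind, "mixture")) curve$weights else 1
  m <- length(comps)
  kind <- integer(m); a <- b <- cc <- numeric(m)
  edges <- values <- vector("list", m)
  for (i in seq_len(m)) {
    ci <- comps[[i]]
    edges[[i]] <- numeric(0); values[[i]] <- numeric(0)
    switch(ci$kind,
      step = { kind[i] <- 1L; a[i] <- ci$low; b[i] <- ci$mid; cc[i] <- ci$high },
      logistic = { kind[i] <- 2L; a[i] <- ci$d; b[i] <- ci$b },
      piecewise_constant = {
        kind[i] <- 3L; edges[[i]] <- ci$edges; values[[i]] <- ci$values
      },
      constant = { kind[i] <- 4L; a[i] <- ci$p },
      identity = { kind[i] <- 5L },
      stop("unknown curve kind: ", ci$kind, call. = FALSE)
    )
  }
  list(kind = kind, a = a, b = b, c = cc, w = as.numeric(w),
       edges = edges, values = values)
}

#' Evaluate an influence curve
#'
#' @param curve An `influence_curve`.
#' @param x Popularity values in \[0, 1\] (vectorized).
#' @return Choice probabilities in \[0, 1\].
#' @export
evaluate_curve <- function(curve, x) {
  stopifnot(inherits(curve, "influence_curve"), is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("popularity x must lie in [0, 1]", call. = FALSE)
  cpp_eval_curve(curve_to_cspec(curve), as.numeric(x))
}

# One-sided limits of f at x = 1/2. Analytic for all primitive kinds; a
# mixture's limits are the weighted means of its components' limits.
curve_limits_at_half <- function(curve) {
  switch(curve$kind,
    step = c(left = curve$low, right = curve$high),
    logistic = {
      v <- evaluate_curve(curve, 0.5)
      c(left = v, right = v)
    },
    piecewise_constant = {
      e <- curve$edges; v <- curve$values
      j <- which(abs(e - 0.5) <= 1e-12)
      if (length(j) == 1 && j > 1 && j < length(e)) {
        c(left = v[j - 1], right = v[j])
      } else {
        val <- evaluate_curve(curve, 0.5)
        c(left = val, right = val)
      }
    },
    constant = c(left = curve$p, right = curve$p),
    identity = c(left = 0.5, right = 0.5),
    mixture = {
      lims <- vapply(curve$components, curve_limits_at_half, numeric(2))
      c(left = sum(curve$weights * lims["left", ]),
        right = sum(curve$weights * lims["right", ]))
    },
    numeric_limits_at_half(curve)
  )
}

# Numeric fallback: geometric offsets eps, eps/2, ..., last value taken.
numeric_limits_at_half <- function(curve, eps = 1e-4, n_halvings = 20) {
  offs <- eps / 2^(0:(n_halvings - 1))
  left <- evaluate_curve(curve, 0.5 - offs)
  right <- evaluate_curve(curve, 0.5 + offs)
  # left values approach the limit from below (nondecreasing f), right from above
  if (any(diff(left) < -1e-9) || any(diff(right) > 1e-9))
    stop("non-monotone limit sequence; cannot estimate one-sided limits",
         call. = FALSE)
  c(left = left[n_halvings], right = right[n_halvings])
}

validate_influence_curve <- function(curve, grid_n = 1001, tol = 1e-12) {
  grid <- seq(0, 1, length.out = grid_n)
  y <- cpp_eval_curve(curve_to_cspec(curve), grid)
  if (any(y < -tol | y > 1 + tol))
    stop("curve evaluations outside [0, 1]", call. = FALSE)
  if (any(diff(y) < -tol))
    stop("curve is not nondecreasing", call. = FALSE)
  lims <- curve_limits_at_half(curve)
  if (lims["left"] > lims["right"] + tol)
    stop("left limit at 1/2 exceeds right limit", call. = FALSE)
  invisible(curve)
}

#' Decompose an influence curve into continuous and marginal-majority parts
#'
#' Writes f(x) = g(x) + (M/2) u(x) with g continuous at x = 1/2 and u the
#' sign step (u = +1 above 1/2, -1 below, 0 at 1/2). M is the jump of f at
#' 1/2 (the marginal majority effect) and d = 1 - 2 g(0.5) is the inherent
#' appeal difference between the two options when equally popular. Because
#' f >= 0 near 1/2, the two always satisfy M + d <= 1.
#'
#' @param curve An `influence_curve`.
#' @param eps Initial offset for numeric one-sided limits (only used for
#'   curve kinds without analytic limits).
#' @return A list of class `curve_decomposition` with elements `M`, `d`,
#'   `g_half`, `left_limit`, `right_limit`, and `c` (the right limit,
#'   g(0.5) + M/2).
#' @export
decompose_curve <- function(curve, eps = 1e-4) {
  stopifnot(inherits(curve, "influence_curve"))
  lims <- curve_limits_at_half(curve)
  M <- unname(lims["right"] - lims["left"])
  g_half <- unname((lims["left"] + lims["right"]) / 2)
  out <- list(M = M, d = 1 - 2 * g_half, g_half = g_half,
              left_limit = unname(lims["left"]),
              right_limit = unname(lims["right"]),
              c = g_half + M / 2)
  class(out) <- "curve_decomposition"
  out
}

#' Feasibility of a (M, d) pair
#'
#' The marginal majority effect M and the inherent appeal difference d of any
#' influence curve with f(0.5) <= 0.5 satisfy M >= 0, d >= 0 and M + d <= 1
#' (f must stay nonnegative just above popularity 1/2).
#'
#' @param M Marginal majority effect.
#' @param d Inherent appeal difference.
#' @return `TRUE` iff the pair is realizable.
#' @export
check_feasibility <- function(M, d) {
  stopifnot(is.numeric(M), is.numeric(d))
  M >= 0 & d >= 0 & (M + d) <= 1
}

#' @export
print.influence_curve <- function(x, ...) {
  cat("<influence_curve:", x$kind, ">\n")
  dec <- decompose_curve(x)
  cat(sprintf("  M = %.4g, d = %.4g, f(0.5-) = %.4g, f(0.5+) = %.4g\n",
              dec$M, dec$d, dec$left_limit, dec$right_limit))
  invisible(x)
}

#' @export
print.curve_decomposition <- function(x, ...) {
  cat(sprintf(
    "curve decomposition: M = %.6g, d = %.6g, g(0.5) = %.6g, c = %.6g\n",
    x$M, x$d, x$g_half, x$c))
  invisible(x)
}

#' Build an influence curve from a configuration list
#'
#' Accepts the JSON-style specification used by the command-line interface:
#' `list(type = "step", low =, high =, mid =)`,
#' `list(type = "logistic", d =, b =)`,
#' `list(type = "piecewise", edges =, values =)`,
#' `list(type = "constant", p =)`, `list(type = "identity")`, or
#' `list(type = "mixture", components = list(...), weights =)`.
#'
#' @param config A named list (e.g. parsed from JSON).
#' @return An `influence_curve`.
#' @export
curve_from_config <- function(config) {
  if (is.null(config$type)) stop("curve config needs a 'type' field", call. = FALSE)
  switch(config$type,
    step = step_curve(config$low, config$high,
                      if (is.null(config$mid)) (config$low + config$high) / 2
                      else config$mid),
    logistic = logistic_curve(config$d, config$b),
    piecewise = piecewise_curve(unlist(config$edges), unlist(config$values)),
    constant = constant_curve(config$p),
    identity = identity_curve(),
    mixture = aggregate_curves(lapply(config$components, curve_from_config),
                               unlist(config$weights)),
    stop("unknown curve type: ", config$type, call. = FALSE)
  )
}
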