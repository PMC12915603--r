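#' Locate and classify equilibria of an influence curve
#'
#' Equilibria are points where the influence curve meets the diagonal y = x.
#' Where the curve crosses the diagonal from above (a downcrossing) the
#' equilibrium is stable: those are the possible long-run popularities of
#' option A. Upcrossings are unstable and act as critical masses separating
#' the basins of attraction. Crossings produced by the jump at x = 1/2
#' (left limit below 1/2, right limit above) are detected from the one-sided
#' limits.
#'
#' @param curve An [influence_curve].
#' @param grid_n Number of grid points used to bracket sign changes of
#'   f(x) - x (>= 100).
#' @param tol Bisection tolerance for crossing locations.
#' @param margin Tangency margin: when |f - x| stays within `margin` on one
#'   side of a crossing, the stability is reported as "indeterminate" rather
#'   than guessed.
#' @return A list of class `equilibrium_report` with `equilibria` (data frame
#'   of `location` and `stability`), `lock_in_prone` (some stable equilibrium
#'   strictly above 1/2), and `critical_mass` (location of the unstable
#'   equilibrium bounding the upper stable basin, `NA` if none).
#' @examples
#' find_equilibria(step_curve(0.45, 0.55))
#' @export
find_equilibria <- function(curve, grid_n = 2001, tol = 1e-9, margin = 1e-6) {
  stopifnot(inherits(curve, "influence_curve"))
  if (grid_n < 100) stop("grid_n must be >= 100", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  g <- function(x) evaluate_curve(curve, x) - x
  xs <- sort(unique(c(seq(0, 1, length.out = grid_n), 0.5)))
  gs <- g(xs)
  locs <- numeric(0)

  # crossings interior to grid cells, refined by bisection
  half <- which(abs(xs - 0.5) <= .Machine$double.eps)
  for (i in seq_len(length(xs) - 1)) {
    a <- xs[i]; bb <- xs[i + 1]
    fa <- gs[i]; fb <- gs[i + 1]
    if (fa == 0) locs <- c(locs, a)
    if (fa > 0 && fb < 0 || fa < 0 && fb > 0) {
      # skip cells abutting 1/2; the jump crossing is handled from limits
      if (abs(a - 0.5) <= tol || abs(bb - 0.5) <= tol) next
      lo <- a; hi <- bb; flo <- fa
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2; fm <- g(mid)
        if (fm == 0) { lo <- hi <- mid; break }
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      locs <- c(locs, (lo + hi) / 2)
    }
  }
  if (gs[length(gs)] == 0) locs <- c(locs, 1)

  # jump crossing at exactly 1/2
  lims <- curve_limits_at_half(curve)
  if ((lims["left"] - 0.5) * (lims["right"] - 0.5) < 0 ||
      abs(evaluate_curve(curve, 0.5) - 0.5) <= tol) {
    locs <- c(locs, 0.5)
  }

  locs <- sort(unique(round(locs / tol) * tol))
  # merge near-duplicates
  if (length(locs) > 1) locs <- locs[c(TRUE, diff(locs) > 10 * tol)]

  # probe offset for stability classification; must exceed the tangency
  # margin so that a transversal crossing of a flat segment (slope -1 of
  # f - x) registers as |g| = delta > margin
  delta <- max(10 * tol, 100 * margin, 1e-4)
  classify <- function(e) {
    xl <- max(0, e - delta); xr <- min(1, e + delta)
    gl <- if (xl < e) g(xl) else NA_real_
    gr <- if (xr > e) g(xr) else NA_real_
    # at the boundary use the inward side only
    if (is.na(gl)) return(if (gr < -margin) "stable" else if (gr > margin) "unstable" else "indeterminate")
    if (is.na(gr)) return(if (gl > margin) "stable" else if (gl < -margin) "unstable" else "indeterminate")
    if (gl > margin && gr < -margin) "stable"
    else if (gl < -margin && gr > margin) "unstable"
    else "indeterminate"
  }
  stab <- vapply(locs, classify, character(1))
  eq <- data.frame(location = locs, stability = stab,
                   stringsAsFactors = FALSE)
  upper_stable <- eq$location[eq$stability == "stable" & eq$location > 0.5]
  lock_in_prone <- length(upper_stable) > 0
  critical_mass <- NA_real_
  if (lock_in_prone) {
    unst <- eq$location[eq$stability == "unstable" &
                          eq$location < min(upper_stable)]
    if (length(unst) > 0) critical_mass <- max(unst)
  }
  structure(list(equilibria = eq, lock_in_prone = lock_in_prone,
                 critical_mass = critical_mass),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium_report>\n")
  print(x$equilibria, row.names = FALSE)
  cat("lock_in_prone:", x$lock_in_prone,
      " critical_mass:", format(x$critical_mass, digits = 6), "\n")
  invisible(x)
}

#' Does a curve enter the lock-in region?
#'
#' The lock-in region is the set y > x > 1/2: a process is lock-in-prone if
#' and only if its influence curve enters it. For step curves this reduces to
#' `high > 1/2`; generic curves are scanned on a fine grid of (1/2, 1),
#' together with the right limit at 1/2 (the curve enters the region
#' immediately to the right of 1/2 whenever that limit exceeds 1/2).
#'
#' @param curve An [influence_curve], or a `binned_curve` from
#'   [bin_influence_curve()].
#' @param grid_n Grid resolution for the scan.
#' @return Logical.
#' @export
enters_lock_in_region <- function(curve, grid_n = 4001) {
  UseMethod("enters_lock_in_region")
}

#' @export
enters_lock_in_region.step_curve <- function(curve, grid_n = 4001) {
  curve$high > 0.5
}

#' @export
enters_lock_in_region.influence_curve <- function(curve, grid_n = 4001) {
  lims <- curve_limits_at_half(curve)
  if (lims["right"] > 0.5) return(TRUE)
  xs <- seq(0.5, 1, length.out = grid_n)[-1]
  any(evaluate_curve(curve, xs) > xs)
}

#' @export
#' @rdname enters_lock_in_region
#' @param method For binned empirical curves: assess the estimate at bin
#'   "midpoints" (default; conservative) or along interpolating "segments"
#'   between bin midpoints.
enters_lock_in_region.binned_curve <- function(curve, grid_n = 4001,
                                               method = c("midpoints", "segments")) {
  method <- match.arg(method)
  b <- curve$bins
  ok <- !is.na(b$estimate) & b$n_eff > 0
  mid <- (b$lower + b$upper) / 2
  upper <- ok & mid > 0.5
  if (!any(upper)) stop("no data above popularity 1/2; lock-in region entry undetermined",
                        call. = FALSE)
  if (method == "midpoints") {
    return(any(b$estimate[upper] > mid[upper]))
  }
  # segments: piecewise-linear interpolation between consecutive estimated midpoints
  xs <- mid[ok]; ys <- b$estimate[ok]
  if (length(xs) < 2) return(any(ys[xs > 0.5] > xs[xs > 0.5]))
  grid <- seq(max(0.5 + 1e-9, min(xs)), max(xs), length.out = grid_n)
  fhat <- stats::approx(xs, ys, xout = grid, rule = 2)$y
  any(grid > 0.5 & fhat > grid)
}

#' Critical logistic slope for lock-in proneness
#'
#' For the logistic influence curve with inherent appeal difference d, finds
#' the smallest slope b at which the curve enters the lock-in region. At the
#' threshold the curve is tangent to the diagonal from below, so b* solves
#' the tangency system f(x) = x and f'(x) = 1; using f' = 2 b f (1 - f) the
#' tangency point satisfies 2 b x (1 - x) = 1, i.e. x = (1 + sqrt(1 - 2/b))/2,
#' and b* is the root of f(x(b)) - x(b). For d = 0 the tangency degenerates
#' to x = 1/2 and b* = 2 exactly.
#'
#' @param d Inherent appeal difference, 0 <= d < 1.
#' @param tol Root-finding tolerance.
#' @return The critical slope b*.
#' @examples
#' logistic_lock_in_threshold(0.2)  # about 2.98, printed as "b > 3"
#' @export
logistic_lock_in_threshold <- function(d, tol = 1e-9) {
  if (!(is.numeric(d) && length(d) == 1 && d >= 0 && d < 1))
    stop("d must lie in [0, 1)", call. = FALSE)
  if (d == 0) return(2)
  gap <- function(b) {
    xt <- (1 + sqrt(1 - 2 / b)) / 2
    evaluate_curve(logistic_curve(d, b), xt) - xt
  }
  # gap is increasing in b: larger slope lifts the curve above 1/2
  lo <- 2 + 1e-9
  hi <- 4
  while (gap(hi) < 0) hi <- hi * 2
  stats::uniroot(gap, c(lo, hi), tol = tol)$root
}
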