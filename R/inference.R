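#' Logistic regression of lock-in on a model quantity
#'
#' Fits a binary (logistic) regression of observed lock-in on a per-item
#' regressor, mirroring the model-comparison protocol: when the regressor is
#' the difference M - d, the theory pins the threshold at 0, so the model is
#' fit without an intercept (one parameter); when the regressor is d alone
#' there is no ex-ante threshold and an intercept is included (two
#' parameters). Goodness of fit is summarized by log-likelihood, AIC, BIC
#' and McFadden's R-squared (against the intercept-only null).
#'
#' @param outcomes Binary vector (0/1 or logical), one per item.
#' @param regressor Numeric vector, one per item.
#' @param with_intercept Include an intercept term?
#' @return A list of class `lockin_logistic_fit` with `coefficients`,
#'   `log_lik`, `aic`, `bic`, `mcfadden_r2`, `fitted`, `separation`
#'   (perfect-separation flag), `k` (parameter count), `n`.
#' @export
fit_lockin_logistic <- function(outcomes, regressor, with_intercept = TRUE) {
  y <- as.numeric(outcomes)
  stopifnot(length(y) == length(regressor), all(y %in% c(0, 1)))
  n <- length(y)
  if (n < 2) stop("need at least two items", call. = FALSE)
  dat <- data.frame(y = y, r = as.numeric(regressor))
  form <- if (with_intercept) y ~ r else y ~ r - 1
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat))
  mu <- stats::fitted(fit)
  eps <- 1e-10
  ll <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  k <- length(stats::coef(fit))
  # perfect separation: fitted values pushed to the boundary on both classes
  sep <- all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6) &&
    stats::sd(y) > 0
  # null model: intercept only (also for the no-intercept fit, so both
  # comparisons share one null)
  p0 <- mean(y)
  ll0 <- if (p0 %in% c(0, 1)) 0 else n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  r2 <- if (ll0 == 0) NA_real_ else 1 - ll / ll0
  structure(list(coefficients = stats::coef(fit), log_lik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 mcfadden_r2 = r2, fitted = mu, separation = sep,
                 k = k, n = n, degenerate = stats::sd(y) == 0),
            class = "lockin_logistic_fit")
}

#' @export
print.lockin_logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: LL = %.4g, AIC = %.4g, BIC = %.4g, McFadden R2 = %.3g%s\n",
              x$log_lik, x$aic, x$bic, x$mcfadden_r2,
              if (x$separation) " [perfect separation]" else ""))
  invisible(x)
}

# Nadaraya-Watson fitted values with a Gaussian kernel.
nw_fitted <- function(x, y, bandwidth, at = x) {
  vapply(at, function(x0) {
    w <- stats::dnorm((x - x0) / bandwidth)
    if (sum(w) == 0) mean(y) else sum(w * y) / sum(w)
  }, numeric(1))
}

# Leave-one-out squared error of the NW estimator at bandwidth h.
nw_loo_sse <- function(x, y, h) {
  n <- length(x)
  sum(vapply(seq_len(n), function(i) {
    w <- stats::dnorm((x[-i] - x[i]) / h)
    pred <- if (sum(w) == 0) mean(y[-i]) else sum(w * y[-i]) / sum(w)
    (y[i] - pred)^2
  }, numeric(1)))
}

#' Nadaraya-Watson kernel regression of lock-in on a model quantity
#'
#' Nonparametric counterpart of [fit_lockin_logistic()]: Gaussian-kernel
#' locally weighted means, with the bandwidth chosen by least-squares
#' leave-one-out cross-validation (golden-section search on a log-spaced
#' range scaled to the regressor's spread; deterministic). For binary
#' outcomes the fitted values are probabilities in \[0, 1\] (convex
#' combinations of the outcomes). The log-likelihood clips fitted values to
#' \[1e-6, 1 - 1e-6\]; the R-squared is the squared correlation between
#' fitted values and outcomes.
#'
#' @inheritParams fit_lockin_logistic
#' @param bandwidth Optional fixed bandwidth (skips cross-validation);
#'   `Inf` yields the global mean for every point.
#' @return A list of class `lockin_kernel_fit` with `bandwidth`, `fitted`,
#'   `log_lik`, `r2`, `n`.
#' @export
fit_lockin_kernel <- function(outcomes, regressor, bandwidth = NULL) {
  y <- as.numeric(outcomes)
  x <- as.numeric(regressor)
  stopifnot(length(y) == length(x), all(y %in% c(0, 1)))
  n <- length(y)
  if (n < 3) stop("need at least three items", call. = FALSE)
  spread <- stats::sd(x)
  if (spread == 0 || length(unique(x)) < 2) {
    fitted <- rep(mean(y), n)
    h <- NA_real_
  } else if (!is.null(bandwidth)) {
    h <- bandwidth
    fitted <- if (is.infinite(h)) rep(mean(y), n) else nw_fitted(x, y, h)
  } else {
    # golden-section search on log h
    lo <- log(spread * 1e-3); hi <- log(spread * 10)
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
    f1 <- nw_loo_sse(x, y, exp(c1)); f2 <- nw_loo_sse(x, y, exp(c2))
    for (it in 1:80) {
      if (f1 < f2) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - phi * (b - a); f1 <- nw_loo_sse(x, y, exp(c1))
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + phi * (b - a); f2 <- nw_loo_sse(x, y, exp(c2))
      }
      if (b - a < 1e-8) break
    }
    h <- exp((a + b) / 2)
    fitted <- nw_fitted(x, y, h)
  }
  pc <- pmin(pmax(fitted, 1e-6), 1 - 1e-6)
  ll <- sum(y * log(pc) + (1 - y) * log(1 - pc))
  r2 <- if (stats::sd(fitted) == 0 || stats::sd(y) == 0) 0
        else stats::cor(fitted, y)^2
  structure(list(bandwidth = h, fitted = fitted, log_lik = ll, r2 = r2,
                 n = n),
            class = "lockin_kernel_fit")
}

#' @export
print.lockin_kernel_fit <- function(x, ...) {
  cat(sprintf("kernel fit: bandwidth = %.4g, LL = %.4g, R2 = %.3g\n",
              x$bandwidth, x$log_lik, x$r2))
  invisible(x)
}

#' Aggregate test of the predicted lock-in frequency
#'
#' Under the theory, each trial of item i locks in with probability at least
#' the item's closed-form bound p_i. The total lock-in count across all
#' trials of all items is then stochastically above a Poisson-binomial
#' variable with the per-trial bounds as success probabilities. The one-sided
#' 95% lower bound on the total count is obtained by simulation: `reps`
#' Poisson-binomial draws, taking the 5% quantile (the 5000th smallest draw
#' at reps = 1e5). Per-item p-values for observing at most k lock-ins in n
#' trials come from the binomial law at the item's bound.
#'
#' @param item_bounds Per-item lower bounds on the lock-in probability.
#' @param trials_per_item Number of trials for each item.
#' @param observed_per_item Observed lock-in counts per item (optional; when
#'   supplied, per-item p-values and the observed total are reported).
#' @param reps Number of simulated Poisson-binomial draws (>= 1e4).
#' @param seed Optional integer seed.
#' @return A list of class `aggregate_lockin_test` with `lower_bound_95`
#'   (one-sided lower confidence bound on the total count),
#'   `expected_total`, `observed_total`, `consistent` (observed >= lower
#'   bound), and `item_p_values` (probability of at most the observed count
#'   under the item's bound).
#' @export
aggregate_lock_in_test <- function(item_bounds, trials_per_item,
                                   observed_per_item = NULL, reps = 1e5,
                                   seed = NULL) {
  stopifnot(length(item_bounds) == length(trials_per_item))
  if (any(item_bounds < 0 | item_bounds > 1))
    stop("bounds must lie in [0, 1]", call. = FALSE)
  if (reps < 1e4) stop("reps must be >= 1e4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # per-trial probability vector: item bound repeated per trial
  totals <- rep(0L, reps)
  for (i in seq_along(item_bounds)) {
    totals <- totals + stats::rbinom(reps, trials_per_item[i], item_bounds[i])
  }
  totals <- sort(totals)
  lower <- totals[max(1L, floor(0.05 * reps))]
  out <- list(lower_bound_95 = lower,
              expected_total = sum(item_bounds * trials_per_item),
              observed_total = if (is.null(observed_per_item)) NA_integer_
                               else sum(observed_per_item),
              consistent = if (is.null(observed_per_item)) NA
                           else sum(observed_per_item) >= lower,
              item_p_values = if (is.null(observed_per_item)) NULL
                              else stats::pbinom(observed_per_item,
                                                 trials_per_item, item_bounds))
  class(out) <- "aggregate_lockin_test"
  out
}

#' @export
print.aggregate_lockin_test <- function(x, ...) {
  cat(sprintf("aggregate lock-in test: 95%% lower bound %d, expected %.1f, observed %s\n",
              x$lower_bound_95, x$expected_total,
              ifelse(is.na(x$observed_total), "-", x$observed_total)))
  invisible(x)
}
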