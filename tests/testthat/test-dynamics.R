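test_that("trials are reproducible and conserve counts", {
  spec <- process_spec(step_curve(0.4, 0.6), horizon = 500)
  t1 <- simulate_trial(spec, seed = 31)
  t2 <- simulate_trial(spec, seed = 31)
  expect_identical(t1$choice, t2$choice)
  expect_identical(t1$end_popularity, t2$end_popularity)

  # popularity times the running total count is an integer count
  tot <- spec$init_a + spec$init_b + seq_len(spec$horizon) - 1
  counts <- t1$x * tot
  expect_equal(counts, round(counts), tolerance = 1e-9)
  nA <- sum(t1$choice == "A")
  expect_equal(t1$end_popularity,
               (spec$init_a + nA) / (spec$init_a + spec$init_b + spec$horizon))

  e1 <- simulate_ensemble(spec, 50, seed = 4)
  e2 <- simulate_ensemble(spec, 50, seed = 4)
  expect_identical(e1$end_popularity, e2$end_popularity)
  expect_error(simulate_ensemble(spec, 0), ">= 1")
})

test_that("a flat curve behaves like i.i.d. Bernoulli choice", {
  spec <- process_spec(constant_curve(0.2), horizon = 1e4)
  tr <- simulate_trial(spec, seed = 17)
  expect_lt(abs(tr$end_popularity - 0.2), 3 * sqrt(0.2 * 0.8 / 1e4))

  # unique stable equilibrium below 1/2: no lock-in
  e <- simulate_ensemble(process_spec(constant_curve(0.2), horizon = 2000),
                         500, seed = 18)
  expect_equal(e$lock_in_count, 0L)
  expect_false(e$lock_in_flag)
})

test_that("the identity curve gives the classical uniform urn limit", {
  spec <- process_spec(identity_curve(), horizon = 2000, init_a = 1,
                       init_b = 1)
  e <- simulate_ensemble(spec, 2000, seed = 41)
  ks <- suppressWarnings(stats::ks.test(e$end_popularity, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensemble means approach the stable equilibrium as horizon grows", {
  err <- vapply(c(200, 2000), function(h) {
    e <- simulate_ensemble(process_spec(constant_curve(0.2), horizon = h),
                           300, seed = 51)
    mean(abs(e$end_popularity - 0.2))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("the auxiliary step process attains the closed-form bound", {
  # curve 0 / (1-d)/2 / (1-d+M)/2 with M = 0.2, d = 0.1 and counts (1, 1)
  # is exactly the boundary walk; survival frequency ~ 0.18/1.39
  spec <- process_spec(step_curve(0, 0.55, mid = 0.45), horizon = 2000)
  e <- simulate_ensemble(spec, 2e4, seed = 61)
  p <- 0.18 / 1.39
  se <- sqrt(p * (1 - p) / 2e4)
  expect_gt(mean(e$survived), p - 3 * se)

  # a symmetric jump-only curve: lock-in frequency at least the M = 0.1,
  # d = 0 bound (0.2/1.3)
  e2 <- simulate_ensemble(process_spec(step_curve(0.45, 0.55), horizon = 2000),
                          2000, seed = 62)
  p2 <- 0.2 / 1.3
  expect_gte(e2$lock_in_count / 2000, p2 - 3 * sqrt(p2 * (1 - p2) / 2000))
})

test_that("lock-in requires strictly entering the region (dichotomy)", {
  # curves with M > d (or entering the region): frequency >= bound - 3 SE;
  # curves that stay out of the region: essentially no lock-in
  inside <- list(c(M = 0.3, d = 0.1), c(M = 0.5, d = 0.2), c(M = 0.15, d = 0))
  for (par in inside) {
    g <- (1 - par["d"]) / 2
    crv <- step_curve(g - par["M"] / 2, g + par["M"] / 2)
    e <- simulate_ensemble(process_spec(crv, horizon = 5000), 1000,
                           seed = 70 + round(100 * par["M"]))
    p <- lock_in_probability_bound(par["M"], par["d"])$p_L_lower
    expect_gte(e$lock_in_count / 1000, p - 3 * sqrt(p * (1 - p) / 1000))
  }
  outside <- list(step_curve(0.2, 0.45), logistic_curve(0.2, 2),
                  constant_curve(0.35))
  for (crv in outside) {
    e <- simulate_ensemble(process_spec(crv, horizon = 5000), 1000, seed = 81)
    expect_lte(e$lock_in_count / 1000, 0.01)
  }
})

test_that("end-of-trial lock-in uses strict inequalities", {
  r <- end_of_trial_lock_in(c(0.40, 0.55))
  expect_true(r$flag); expect_equal(r$count, 1)
  expect_false(end_of_trial_lock_in(c(0.50, 0.49))$flag)
  r3 <- end_of_trial_lock_in(c(-0.1, 0.0, 0.02), threshold = 0)
  expect_true(r3$flag); expect_equal(r3$count, 1)
  expect_error(end_of_trial_lock_in(numeric(0)), "empty")
})

test_that("party-signal process respects symmetry and absorbing limits", {
  # symmetric parameters: end support difference symmetric about 0
  ps <- party_spec(0.7, 0.3, 0.3, 0.7, horizon = 200)
  e <- simulate_party_ensemble(ps, 400, seed = 91)
  st <- stats::binom.test(sum(e$ybar > 0), sum(e$ybar != 0))
  expect_gt(st$p.value, 0.01)

  # deterministic support: party A always supports, party B never
  pd <- party_spec(1, 1, 0, 0, horizon = 100)
  tr <- simulate_party_trial(pd, seed = 92)
  expect_equal(tr$ybar, 1)

  expect_error(party_spec(1.2, 0, 0, 0, horizon = 10), "\\[0, 1\\]")
})

test_that("party process mapped from (M, d) attains the bound", {
  M <- 0.3; d <- 0.05
  ps <- party_spec_from_md(M, d, horizon = 1000, assignment = "alternating")
  expect_equal(ps$p_plus_a, (1 - d + M) / 2)
  expect_equal(ps$p_minus_b, (1 + d + M) / 2)
  e <- simulate_party_ensemble(ps, 600, seed = 101)
  p <- lock_in_probability_bound(M, d)$p_L_lower
  expect_gte(e$lock_in_count / 600, p - 3 * sqrt(p * (1 - p) / 600))
})
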