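test_that("running popularity counts prior choices plus artificial seeding", {
  ct <- make_table(worlds = list(w1 = "AB"), init = list(w1 = c(110, 10)))
  rec <- attach_running_popularity(ct)
  expect_equal(rec$x[1], 110 / 120)
  expect_equal(rec$x[2], 111 / 121)

  ct2 <- make_table(worlds = list(w1 = "AB"))
  rec2 <- attach_running_popularity(ct2)
  expect_true(is.na(rec2$x[1]))  # unseeded world: first participant undefined
  expect_equal(rec2$x[2], 1)

  ct3 <- make_table(worlds = list(w1 = "AB"), init = list(w1 = c(1, 1)))
  rec3 <- attach_running_popularity(ct3)
  expect_equal(rec3$x, c(0.5, 2 / 3))

  # contiguity is enforced at construction
  bad <- data.frame(item_id = "i", world_id = "w", t = c(1, 3),
                    choice = c("A", "B"), condition = "social")
  expect_error(choice_table(bad), "contiguous")
})

test_that("binning weights records, halves edge cases, drops the tie point", {
  rec <- data.frame(x = c(0.31, 0.33, 0.38, 0.39),
                    choice = c("A", "A", "A", "B"))
  b <- bin_influence_curve(rec)
  row <- b$bins[abs(b$bins$lower - 0.3) < 1e-9, ]
  expect_equal(row$estimate, 0.75)
  expect_equal(row$n_eff, 4)
  expect_equal(row$se, sqrt(0.75 * 0.25 / 4))

  # exact interior edge: half weight in each adjacent bin
  b2 <- bin_influence_curve(data.frame(x = 0.4, choice = "A"))
  expect_equal(b2$bins$n_eff[abs(b2$bins$lower - 0.3) < 1e-9], 0.5)
  expect_equal(b2$bins$n_eff[abs(b2$bins$lower - 0.4) < 1e-9], 0.5)

  # x = 0.5 is excluded by default, kept on request
  b3 <- bin_influence_curve(data.frame(x = c(0.5, 0.55), choice = c("A", "A")))
  expect_equal(sum(b3$bins$n_eff), 1)
  b4 <- bin_influence_curve(data.frame(x = c(0.5, 0.55), choice = c("A", "A")),
                            exclude_half = FALSE)
  expect_equal(sum(b4$bins$n_eff), 2)

  # empty bins report no estimate, not zero
  expect_true(is.na(b2$bins$estimate[1]))

  # weight conservation, exact, on a mix of edge and interior records
  set.seed(12)
  x <- c(runif(200), seq(0.1, 0.9, by = 0.1), 0, 1)
  rec5 <- data.frame(x = x, choice = sample(c("A", "B"), length(x), TRUE))
  b5 <- bin_influence_curve(rec5, exclude_half = FALSE)
  expect_identical(sum(b5$bins$n_eff), as.numeric(length(x)))
  b6 <- bin_influence_curve(rec5, exclude_half = TRUE)
  expect_identical(sum(b6$bins$n_eff), as.numeric(length(x) - sum(x == 0.5)))
})

test_that("M is the central-bin jump with binomial quadrature error", {
  rec <- data.frame(x = c(rep(0.45, 20), rep(0.55, 20)),
                    choice = c(rep("A", 8), rep("B", 12),
                               rep("A", 11), rep("B", 9)))
  b <- bin_influence_curve(rec)
  m <- estimate_M(b)
  expect_equal(m$M, 0.55 - 0.40)
  expect_equal(m$se, sqrt(0.4 * 0.6 / 20 + 0.55 * 0.45 / 20))

  # an empty central bin is an estimation error, not a zero
  b2 <- bin_influence_curve(data.frame(x = rep(0.45, 5), choice = rep("A", 5)))
  expect_error(estimate_M(b2), "no data")
})

test_that("option A and d come from the control condition", {
  ch <- c(rep("A", 30), rep("B", 70))
  r <- estimate_d_and_option_a(ch)
  expect_equal(r$option_a, "A")
  expect_equal(r$d, 0.4)
  expect_false(r$tie)

  # the label with fewer control choices becomes A even if stored as "B"
  r2 <- estimate_d_and_option_a(c(rep("A", 70), rep("B", 30)))
  expect_equal(r2$option_a, "B")
  expect_equal(r2$d, 0.4)

  r3 <- estimate_d_and_option_a(c(rep("A", 50), rep("B", 50)))
  expect_equal(r3$d, 0)
  expect_equal(r3$option_a, "A")  # lexicographic tie-break
  expect_true(r3$tie)

  expect_error(estimate_d_and_option_a(character(0)), "empty")

  # consistency for d = 1 - 2 g(0.5): control Bernoulli with p = 0.4
  set.seed(13)
  ch4 <- ifelse(stats::rbinom(1e4, 1, 0.4) == 1, "A", "B")
  r4 <- estimate_d_and_option_a(ch4)
  expect_lt(abs(r4$d - 0.2), 3 * r4$se)
})

test_that("M and d estimators recover the generator truth", {
  design <- experiment_design(
    n_items = 30,
    blocks = list(list(n_worlds = 40, participants = 200,
                       init_a = 1, init_b = 1)),
    control_n = 500, M_range = c(0.2, 0.2), d_range = c(0, 0))
  fix <- generate_experiment(design, seed = 14)
  est <- estimate_items(fix$table)
  covered_M <- abs(est$M - 0.2) <= 2 * est$M_se
  covered_d <- abs(est$d - 0) <= 2 * est$d_se
  expect_gte(mean(covered_M), 0.9)
  expect_gte(mean(covered_d), 0.9)
})

test_that("party estimates implement the two-proportion formulas", {
  M <- 0.3; d <- 0.1
  design <- experiment_design(
    n_items = 8,
    blocks = list(list(n_worlds = 8, participants = 230)),
    control_n = 400, M_range = c(M, M), d_range = c(d, d), party = TRUE)
  fix <- generate_experiment(design, seed = 15)
  per_item <- lapply(unique(fix$table$records$item_id), function(it) {
    sub <- choice_table(
      fix$table$records[fix$table$records$item_id == it, , drop = FALSE])
    party_estimates(sub)
  })
  Ms <- vapply(per_item, `[[`, numeric(1), "M")
  ds <- vapply(per_item, `[[`, numeric(1), "d")
  Mse <- vapply(per_item, `[[`, numeric(1), "M_se")
  dse <- vapply(per_item, `[[`, numeric(1), "d_se")
  expect_gte(mean(abs(Ms - M) <= 2 * Mse), 0.75)
  expect_gte(mean(abs(ds - d) <= 2 * dse), 0.75)
  # M = (M_A - M_B)/2 arithmetic
  pe <- per_item[[1]]
  expect_equal(pe$M, (pe$M_a - pe$M_b) / 2)

  # fully symmetric parties: d consistent with 0
  sym <- experiment_design(
    n_items = 4, blocks = list(list(n_worlds = 8, participants = 230)),
    control_n = 400, M_range = c(0.3, 0.3), d_range = c(0, 0), party = TRUE)
  fsym <- generate_experiment(sym, seed = 16)
  dsym <- vapply(unique(fsym$table$records$item_id), function(it) {
    sub <- choice_table(
      fsym$table$records[fsym$table$records$item_id == it, , drop = FALSE])
    pe <- party_estimates(sub)
    abs(pe$d) <= 2 * pe$d_se
  }, logical(1))
  expect_gte(mean(dsym), 0.75)
})

test_that("items are cross-tabulated by criterion versus observed lock-in", {
  est <- data.frame(item_id = c("a", "b", "c"),
                    M = c(0.3, 0.0, NA), d = c(0.1, 0.4, 0.2),
                    lock_in_observed = c(TRUE, FALSE, FALSE))
  cl <- classify_items(est)
  expect_equal(unname(cl$table["TRUE", "TRUE"]), 1)
  expect_equal(unname(cl$table["FALSE", "FALSE"]), 1)
  expect_equal(unname(cl$table["TRUE", "FALSE"]), 0)
  expect_equal(unname(cl$table["FALSE", "TRUE"]), 0)
  expect_equal(cl$no_estimate, 1)
})

test_that("the pipeline separates items with and without lock-in proneness", {
  d_hi <- experiment_design(
    n_items = 8, blocks = list(list(n_worlds = 30, participants = 500,
                                    init_a = 1, init_b = 1)),
    control_n = 300, M_range = c(0.25, 0.35), d_range = c(0, 0.08))
  d_lo <- experiment_design(
    n_items = 8, blocks = list(list(n_worlds = 30, participants = 500,
                                    init_a = 1, init_b = 1)),
    control_n = 300, M_range = c(0, 0.08), d_range = c(0.25, 0.35))
  f_hi <- generate_experiment(d_hi, seed = 17)
  f_lo <- generate_experiment(d_lo, seed = 18)
  est_hi <- estimate_items(f_hi$table)
  est_lo <- estimate_items(f_lo$table)
  # lock-in observed for a majority of M > d items, rarely otherwise
  expect_gte(mean(est_hi$lock_in_observed), 0.5)
  expect_lte(mean(est_lo$lock_in_observed), 0.2)
  # and the estimated criterion agrees with the generator's partition
  expect_gte(mean(est_hi$M > est_hi$d, na.rm = TRUE), 0.9)
  expect_gte(mean(est_lo$M < est_lo$d, na.rm = TRUE), 0.9)
})
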