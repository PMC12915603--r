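test_that("preset designs reproduce the published layouts", {
  v <- design_v2019()
  expect_equal(v$n_items, 7L)
  expect_equal(length(v$blocks), 2)
  expect_equal(v$blocks[[2]]$init_a, 110)
  expect_equal(v$blocks[[2]]$init_b, 10)
  expect_equal(v$blocks[[2]]$participants, 3500)

  m <- design_mdrt2019()
  expect_equal(m$n_items, 20L)
  expect_true(m$party)
  expect_equal(m$blocks[[1]]$n_worlds, 8)
  expect_equal(m$blocks[[1]]$participants, 230)

  fv <- design_fv2021()
  expect_equal(fv$n_items, 30L)
  fix <- generate_experiment(fv, seed = 30)
  nw <- tapply(fix$table$records$world_id[fix$table$records$condition == "social"],
               fix$table$records$item_id[fix$table$records$condition == "social"],
               function(w) length(unique(w)))
  expect_true(all(nw >= 30 & nw <= 45))

  expect_error(experiment_design(5, list(list(n_worlds = 2, participants = 10)),
                                 M_range = c(0, 0.6), d_range = c(0, 0.6)),
               "infeasible")
})

test_that("a V2019-like fixture has the artificial initial advantage", {
  fix <- generate_experiment(design_v2019(), seed = 31)
  rec <- fix$table$records
  expect_equal(length(unique(rec$item_id)), 7)
  soc <- rec[rec$condition == "social", ]
  expect_equal(length(unique(soc$world_id)), 2)
  expect_true(all(fix$table$init$init_a == 110))
  # the seeded world's first participant sees popularity 110/120
  x <- attach_running_popularity(fix$table)
  seeded <- x[x$world_id == "w02" & x$t == 1, ]
  expect_equal(unique(seeded$x), 110 / 120)
})

test_that("fixture truth is self-consistent with the curve decomposition", {
  fix <- generate_experiment(
    experiment_design(6, list(list(n_worlds = 2, participants = 50)),
                      control_n = 50), seed = 32)
  for (i in seq_len(nrow(fix$truth))) {
    tr <- fix$truth[i, ]
    dec <- decompose_curve(step_curve(tr$low, tr$high, tr$mid))
    expect_equal(dec$M, tr$M, tolerance = 1e-12)
    expect_equal(dec$d, tr$d, tolerance = 1e-12)
    if (tr$mm_condition) {
      expect_equal(tr$p_L_lower,
                   lock_in_probability_bound(tr$M, tr$d)$p_L_lower)
    } else {
      expect_true(is.na(tr$p_L_lower))
    }
  }
})

test_that("identical master seeds give byte-identical fixture files", {
  d <- experiment_design(3, list(list(n_worlds = 2, participants = 40,
                                      init_a = 5, init_b = 1)),
                         control_n = 30)
  f1 <- generate_experiment(d, seed = 33)
  f2 <- generate_experiment(d, seed = 33)
  p1 <- file.path(tempdir(), "fix1.csv")
  p2 <- file.path(tempdir(), "fix2.csv")
  write_choice_table(f1$table, p1)
  write_choice_table(f2$table, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(sub("\\.csv$", "_init.json", p1)),
                   readLines(sub("\\.csv$", "_init.json", p2)))
  f3 <- generate_experiment(d, seed = 34)
  expect_false(identical(f1$table$records$choice, f3$table$records$choice))
})

test_that("choice tables round-trip through CSV + sidecar losslessly", {
  fix <- generate_experiment(
    experiment_design(2, list(list(n_worlds = 2, participants = 30,
                                   init_a = 110, init_b = 10)),
                      control_n = 20), seed = 35)
  p <- file.path(tempdir(), "roundtrip.csv")
  write_choice_table(fix$table, p)
  back <- read_choice_table(p)
  expect_equal(back$records$choice, fix$table$records$choice)
  expect_equal(back$records$t, fix$table$records$t)
  expect_equal(back$init$init_a, fix$table$init$init_a)

  # schema violations are named
  bad <- fix$table$records
  bad$t[bad$world_id == "w01" & bad$t == 2 & bad$item_id == "item01"] <- 99
  pb <- file.path(tempdir(), "bad.csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_choice_table(pb), "item01")

  bad2 <- fix$table$records
  bad2$choice[3] <- "C"
  utils::write.csv(bad2, pb, row.names = FALSE)
  expect_error(read_choice_table(pb), "unknown choice")

  utils::write.csv(data.frame(a = 1), pb, row.names = FALSE)
  expect_error(read_choice_table(pb), "missing headers")

  # missing sidecar: defaults with a warning on request
  p2 <- file.path(tempdir(), "nosidecar.csv")
  utils::write.csv(fix$table$records, p2, row.names = FALSE)
  expect_warning(read_choice_table(p2, warn_missing_init = TRUE),
                 "initial counts")
})

test_that("end-to-end: estimation recovers the generator's M > d partition", {
  design <- experiment_design(
    n_items = 20,
    blocks = list(list(n_worlds = 50, participants = 200,
                       init_a = 1, init_b = 1)),
    control_n = 400, M_range = c(0, 0.45), d_range = c(0, 0.45))
  fix <- generate_experiment(design, seed = 36)
  est <- estimate_items(fix$table)
  truth <- fix$truth[match(est$item_id, fix$truth$item_id), ]
  est_mm <- est$M > est$d
  agree <- est_mm == truth$mm_condition
  # items with an identifiable margin (true |M - d| beyond twice the typical
  # estimation error) must classify correctly at >= 90%; any disagreement at
  # all must sit near the M = d boundary
  margin <- abs(truth$M - truth$d) > 0.1
  expect_gte(mean(agree[margin], na.rm = TRUE), 0.9)
  expect_true(all(abs(truth$M - truth$d)[!agree] < 0.1, na.rm = TRUE))
  expect_gte(mean(agree, na.rm = TRUE), 0.75)
  cl <- classify_items(est)
  expect_equal(sum(cl$table) + cl$no_estimate, nrow(est))
})
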