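# Small in-code fixtures for the estimation tests.

# A one-item choice table from explicit per-world choice strings.
make_table <- function(worlds, control = NULL, init = NULL,
                       item = "item01") {
  recs <- list()
  for (w in names(worlds)) {
    ch <- strsplit(worlds[[w]], "")[[1]]
    recs[[length(recs) + 1]] <- data.frame(
      item_id = item, world_id = w, t = seq_along(ch), choice = ch,
      condition = "social", stringsAsFactors = FALSE)
  }
  if (!is.null(control)) {
    ch <- strsplit(control, "")[[1]]
    recs[[length(recs) + 1]] <- data.frame(
      item_id = item, world_id = "control", t = seq_along(ch), choice = ch,
      condition = "control", stringsAsFactors = FALSE)
  }
  init_df <- NULL
  if (!is.null(init)) {
    init_df <- data.frame(item_id = item, world_id = names(init),
                          init_a = vapply(init, `[`, numeric(1), 1),
                          init_b = vapply(init, `[`, numeric(1), 2),
                          stringsAsFactors = FALSE)
  }
  choice_table(do.call(rbind, recs), init_df)
}

# Random step curves with feasible (M, d), for property loops.
random_step_curves <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    d <- runif(1, 0, 0.5)
    M <- runif(1, 0, 1 - d)
    g <- (1 - d) / 2
    step_curve(g - M / 2, g + M / 2)
  })
}
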