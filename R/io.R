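#' Write a choice table to CSV (with a JSON sidecar for world seeding)
#'
#' The records go to a UTF-8 comma-separated file with a mandatory header
#' (`item_id, world_id, t, choice, condition[, party]`). Per-world initial
#' artificial counts go to a sidecar JSON file next to it (same path with
#' `_init.json` instead of `.csv`), keeping the table strictly long-format.
#'
#' @param ct A [choice_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_choice_table <- function(ct, path) {
  stopifnot(inherits(ct, "choice_table"))
  utils::write.csv(ct$records, path, row.names = FALSE, quote = FALSE)
  if (nrow(ct$init) > 0) {
    jsonlite::write_json(ct$init, init_sidecar_path(path), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

init_sidecar_path <- function(path) {
  sub("\\.csv$", "_init.json", path)
}

#' Read a choice table from CSV
#'
#' Validates the schema: required headers present, `t` contiguous from 1
#' within each (item, world, condition), and `choice` restricted to "A"/"B".
#' Violations raise errors that name the offending rows or worlds. A missing
#' sidecar file means no artificial initial counts (defaults of 0 with a
#' warning when `warn_missing_init` is set).
#'
#' @param path CSV path written by [write_choice_table()].
#' @param warn_missing_init Warn when no `_init.json` sidecar is found.
#' @return A [choice_table].
#' @export
read_choice_table <- function(path, warn_missing_init = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("item_id", "world_id", "t", "choice", "condition")
  miss <- setdiff(req, names(rec))
  if (length(miss) > 0)
    stop("missing headers in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!rec$choice %in% c("A", "B"))
  if (length(bad) > 0)
    stop("unknown choice codes at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  rec$item_id <- as.character(rec$item_id)
  rec$world_id <- as.character(rec$world_id)
  ip <- init_sidecar_path(path)
  init <- NULL
  if (file.exists(ip)) {
    init <- jsonlite::fromJSON(ip)
    init$item_id <- as.character(init$item_id)
    init$world_id <- as.character(init$world_id)
  } else if (warn_missing_init) {
    warning("no init sidecar found; assuming initial counts (0, 0)",
            call. = FALSE)
  }
  choice_table(rec, init)
}
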