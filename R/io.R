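# Interaction-log I/O and the two command-line entry points.

LOG_COLUMNS <- c("time", "scenario", "sender", "receiver", "count")

# Validate/coerce a log-like data.frame. `time` may be an integer round
# index or ISO-8601 timestamps (converted to numeric seconds so half-open
# windows work either way).
as_interaction_log <- function(log) {
  if (!is.data.frame(log) || !all(LOG_COLUMNS %in% names(log)))
    stop("interaction log must be a data.frame with columns ",
         paste(LOG_COLUMNS, collapse = ", "), call. = FALSE)
  log <- as.data.frame(log)[, LOG_COLUMNS]
  if (is.character(log$time)) {
    num <- suppressWarnings(as.numeric(log$time))
    if (anyNA(num)) {
      ts <- as.POSIXct(log$time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                      "%Y-%m-%d"))
      if (anyNA(ts))
        stop("time column must be numeric round indices or ISO-8601 ",
             "timestamps; offending rows: ",
             paste(utils::head(which(is.na(ts)), 5), collapse = ", "),
             call. = FALSE)
      num <- as.numeric(ts)
    }
    log$time <- num
  }
  log$sender <- as.character(log$sender)
  log$receiver <- as.character(log$receiver)
  cnt <- suppressWarnings(as.numeric(log$count))
  bad <- which(is.na(cnt) | cnt < 1 | cnt != round(cnt))
  if (length(bad))
    stop("count must be a positive integer; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  log$count <- as.integer(cnt)
  log
}

# read.csv with a required header and a per-line field-count check, so a
# truncated or ragged file fails naming the bad line.
read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"",
                            blank.lines.skip = FALSE)
  bad <- which(!is.na(nf) & nf != length(columns))
  if (length(bad))
    stop("malformed CSV ", path, ": expected ", length(columns),
         " comma-separated fields but line ", bad[1], " has ", nf[bad[1]],
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), columns))
    stop("bad header in ", path, ": expected ",
         paste(columns, collapse = ","), call. = FALSE)
  df
}

#' Read or write an interaction log
#'
#' Two dialects, auto-detected by extension: CSV with header
#' `time,scenario,sender,receiver,count` (`.csv`) and JSON-lines with one
#' record object per line (`.jsonl`/`.ndjson`/`.json`). `time` is an integer
#' round index (ISO-8601 timestamps are also accepted on read and converted
#' to numeric seconds); `count` is a positive integer. Read-write round
#' trips preserve every record exactly.
#'
#' @param path File path; extension selects the dialect.
#' @return `read_interaction_log()` returns the log `data.frame`;
#'   `write_interaction_log()` returns `path` invisibly.
#' @export
read_interaction_log <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read_checked_csv(path, LOG_COLUMNS)
  } else if (ext %in% c("jsonl", "ndjson", "json")) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop("malformed JSON on line ", i, " of ", path, ": ",
                             conditionMessage(e), call. = FALSE))
      if (!all(LOG_COLUMNS %in% names(rec)))
        stop("record on line ", i, " of ", path, " is missing fields: ",
             paste(setdiff(LOG_COLUMNS, names(rec)), collapse = ", "),
             call. = FALSE)
      rec[LOG_COLUMNS]
    })
    df <- do.call(rbind.data.frame, c(recs, stringsAsFactors = FALSE))
    names(df) <- LOG_COLUMNS
  } else stop("unsupported log extension: ", path, call. = FALSE)
  num <- suppressWarnings(as.numeric(df$time))
  if (!anyNA(num)) df$time <- num
  as_interaction_log(df)
}

#' @rdname read_interaction_log
#' @param log Interaction log `data.frame`.
#' @export
write_interaction_log <- function(log, path) {
  log <- as_interaction_log(log)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  } else if (ext %in% c("jsonl", "ndjson", "json")) {
    lines <- vapply(seq_len(nrow(log)), function(i)
      as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                    digits = 12)),
      character(1))
    writeLines(lines, path)
  } else stop("unsupported log extension: ", path, call. = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A small JSON provenance record written alongside every output set: tool
#' version, a platform-stable MD5 hash of the canonical JSON rendering of
#' the configuration, the seed, input/output paths and a timestamp.
#'
#' @param config A [game_config()] (or any serializable list).
#' @param paths Named character vector/list of the files written.
#' @param path Output path of the manifest itself.
#' @export
write_manifest <- function(config, paths, path) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  manifest <- list(
    tool = "gamenet",
    version = as.character(utils::packageVersion("gamenet")),
    config_hash = unname(tools::md5sum(tmp)),
    seed = if (inherits(config, "game_config")) config$seed else NULL,
    paths = as.list(paths),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Run the simulator from a configuration file
#'
#' The `simulate` entry point of the command-line workflow: reads a YAML or
#' JSON game configuration, plays the game, and writes five files into
#' `out_dir` — `log.csv`, `scores.csv`, `events.jsonl`, `roster.csv` and
#' `manifest.json`. Identical config and seed give byte-identical logs.
#'
#' @param config_path Path to the game configuration (YAML or JSON).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly 0 on success; errors propagate (the wrapper script
#'   turns them into a nonzero exit status).
#' @export
cli_simulate <- function(config_path, out_dir) {
  config <- read_game_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- simulate_game(config)
  paths <- c(log = file.path(out_dir, "log.csv"),
             scores = file.path(out_dir, "scores.csv"),
             events = file.path(out_dir, "events.jsonl"),
             roster = file.path(out_dir, "roster.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_interaction_log(run$log, paths[["log"]])
  utils::write.csv(run$scores, paths[["scores"]], row.names = FALSE,
                   quote = FALSE)
  writeLines(vapply(seq_len(nrow(run$events)), function(i)
    as.character(jsonlite::toJSON(as.list(run$events[i, ]),
                                  auto_unbox = TRUE, digits = 12)),
    character(1)), paths[["events"]])
  write_roster(run$roster, paths[["roster"]])
  write_manifest(config, paths, paths[["manifest"]])
  invisible(0L)
}

#' Evaluate recorded interactions from files
#'
#' The `evaluate` entry point: reads an interaction log and roster, runs
#' [evaluate_game()], and writes `<out_prefix>.json` (machine-readable
#' report), `<out_prefix>.txt` (human-readable rendering) and
#' `<out_prefix>_snapshots.csv` (tidy snapshot series). With `table1 = N` it
#' additionally prints the focal-versus-all-ties line for a network of size
#' N under the printed convention.
#'
#' @param log_path,roster_path Input files (see [read_interaction_log()],
#'   [read_roster()]).
#' @param out_prefix Output path prefix.
#' @param window_length,cumulative,directed,focal_convention Passed to
#'   [evaluate_game()].
#' @param table1 Optional integer network size for a [focal_vs_all()] line
#'   printed to standard output.
#' @return Invisibly 0 on success.
#' @export
cli_evaluate <- function(log_path, roster_path, out_prefix,
                         window_length = 5, cumulative = FALSE,
                         directed = FALSE,
                         focal_convention = "self_consistent",
                         table1 = NULL) {
  log <- read_interaction_log(log_path)
  roster <- read_roster(roster_path)
  report <- evaluate_game(log, roster, window_length = window_length,
                          cumulative = cumulative, directed = directed,
                          focal_convention = focal_convention)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  write_evaluation_report(report, paste0(out_prefix, ".json"))
  writeLines(utils::capture.output(print(report)), paste0(out_prefix, ".txt"))
  utils::write.csv(as.data.frame(report$snapshots),
                   paste0(out_prefix, "_snapshots.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(table1)) {
    fc <- focal_vs_all(as.integer(table1), convention = "printed")
    cat(sprintf("N=%d: focal %d, all %d\n", fc$n, fc$focal_ties, fc$all_ties))
  }
  invisible(0L)
}
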