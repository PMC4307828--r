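#' Longitudinal density/diversity snapshots
#'
#' Both measures are cross-sectional: they capture the collaboration
#' structure at one point. Repeated application over consecutive time
#' windows turns them longitudinal — how density rises after the game
#' starts, or how soon interactions die down. The round span of the log is
#' partitioned into consecutive half-open windows `[start, start + w)` (the
#' last may be shorter); per window the package computes density, diversity
#' and the exchange total. A silent window has a defined density of 0 but no
#' defined diversity (evenness of nothing), recorded as `NA`.
#'
#' With `cumulative = TRUE` every window is `[span_start, window_end)`, so
#' ties only accumulate and density is nondecreasing — the natural view for
#' "how connected has the network become", while per-window mode shows
#' die-down.
#'
#' @param log Nonempty interaction log `data.frame`.
#' @param roster An [actor_roster()]; diversity is normalized by the
#'   roster-wide possible-tie count (all enrolled players, including
#'   window-silent ones).
#' @param window_length Window length in rounds (>= 1).
#' @param directed Logical, passed to [build_tie_matrix()].
#' @param cumulative Logical; see above.
#' @return An object of class `snapshot_series`: a `data.frame` with columns
#'   `window_start`, `window_end`, `exchanges`, `actual_ties`, `den`, `div`
#'   and attributes `directed`, `cumulative`, `window_length`.
#' @export
#' @examples
#' run <- simulate_game(aca_game_config(seed = 3))
#' snapshot_series(run$log, run$roster, window_length = 5)
snapshot_series <- function(log, roster, window_length, directed = FALSE,
                            cumulative = FALSE) {
  log <- as_interaction_log(log)
  if (!nrow(log))
    stop("empty log: compute an overall summary on an empty network instead ",
         "of a longitudinal series", call. = FALSE)
  roster <- as_roster(roster, require_n = 2L)
  if (!is.numeric(window_length) || length(window_length) != 1 ||
      is.na(window_length) || window_length < 1)
    stop("window_length must be a single value >= 1", call. = FALSE)
  span0 <- min(log$time); span1 <- max(log$time) + 1
  starts <- seq(span0, span1 - 1e-9, by = window_length)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_length, span1)
    win <- if (cumulative) c(span0, e) else c(s, e)
    m <- build_tie_matrix(log, roster, window = win, directed = directed)
    W <- total_weight(m)
    den <- network_density(m)
    div <- if (W >= 1 && possible_ties(nrow(roster), directed) >= 2)
      network_diversity(m)$div else NA_real_
    data.frame(window_start = s, window_end = e, exchanges = W,
               actual_ties = den$actual_ties, den = den$density, div = div)
  })
  out <- do.call(rbind, rows)
  attr(out, "directed") <- directed
  attr(out, "cumulative") <- cumulative
  attr(out, "window_length") <- window_length
  class(out) <- c("snapshot_series", "data.frame")
  out
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf("Snapshot series (%s%s windows of %g round(s)):\n",
              if (isTRUE(attr(x, "cumulative"))) "cumulative " else "",
              if (isTRUE(attr(x, "directed"))) "directed" else "undirected",
              attr(x, "window_length")))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.snapshot_series <- function(x, ...) {
  mid <- (x$window_start + x$window_end) / 2
  graphics::plot(mid, x$den, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "round", ylab = "value",
                 main = "Network density and diversity over time", ...)
  graphics::lines(mid, x$div, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c("DEN", "DIV"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Evaluate a recorded game
#'
#' The researcher-side evaluation workflow in one call: overall density and
#' diversity, the same per scenario, a longitudinal snapshot series,
#' role-pair collaboration matrices per scenario, and the focal-organization
#' versus whole-network tie comparison for the roster size. Deterministic
#' given its inputs — every number in the report is recomputable from the
#' log and roster alone.
#'
#' @param log Interaction log `data.frame`.
#' @param roster An [actor_roster()] consistent with the log.
#' @param window_length Snapshot window length in rounds (default 5).
#' @param cumulative Logical; cumulative snapshot windows (default `FALSE`).
#' @param directed Logical; analyze directional ties (default `FALSE`).
#' @param scenarios Optional character vector of expected scenario labels; a
#'   log scenario absent from it is an error naming the offender. Default:
#'   the labels present in the log.
#' @param focal_convention Convention for [focal_vs_all()];
#'   `"self_consistent"` (default) or `"printed"`.
#' @return An object of class `game_evaluation`: list with `n_actors`,
#'   `total_exchanges`, `overall` (`den`, `div` results), `per_scenario`
#'   (named list of `den`/`div`/`role_pairs`), `snapshots`
#'   ([snapshot_series()]), `focal` ([focal_vs_all()]), `warnings`
#'   (character), and an `options` echo.
#' @export
#' @examples
#' run <- simulate_game(aca_game_config(seed = 11))
#' ev <- evaluate_game(run$log, run$roster)
#' ev$overall$den$density
evaluate_game <- function(log, roster, window_length = 5, cumulative = FALSE,
                          directed = FALSE, scenarios = NULL,
                          focal_convention = c("self_consistent", "printed")) {
  focal_convention <- match.arg(focal_convention)
  log <- as_interaction_log(log)
  roster <- as_roster(roster, require_n = 2L)
  present <- unique(log$scenario)
  if (is.null(scenarios)) scenarios <- present
  extra <- setdiff(present, scenarios)
  if (length(extra))
    stop("log contains scenario(s) not in the configured list: ",
         paste(sort(extra), collapse = ", "), call. = FALSE)
  warnings <- character()

  m_all <- build_tie_matrix(log, roster, directed = directed)
  den_all <- network_density(m_all)
  div_all <- if (total_weight(m_all) >= 1) network_diversity(m_all) else {
    warnings <- c(warnings, "silent network: overall diversity undefined")
    NULL
  }

  per_scenario <- lapply(scenarios, function(sc) {
    m <- tryCatch(
      build_tie_matrix(log, roster, scenario = sc, directed = directed),
      error = function(e) stop("scenario ", dQuote(sc), ": ",
                               conditionMessage(e), call. = FALSE))
    den <- network_density(m)
    div <- if (total_weight(m) >= 1) network_diversity(m) else NULL
    if (is.null(div))
      warnings <<- c(warnings,
                     paste0("scenario ", dQuote(sc),
                            " is silent: diversity undefined"))
    list(den = den, div = div,
         role_pairs = role_pair_counts(log, roster, scenario = sc))
  })
  names(per_scenario) <- scenarios

  snapshots <- if (nrow(log)) {
    s <- snapshot_series(log, roster, window_length, directed = directed,
                         cumulative = cumulative)
    silent <- sum(s$exchanges == 0)
    if (silent > 0)
      warnings <- c(warnings,
                    paste0(silent, " silent window(s): diversity undefined"))
    s
  } else NULL

  structure(list(
    n_actors = nrow(roster),
    total_exchanges = sum(log$count[log$sender != log$receiver]),
    overall = list(den = den_all, div = div_all),
    per_scenario = per_scenario,
    snapshots = snapshots,
    focal = focal_vs_all(nrow(roster), convention = focal_convention),
    warnings = warnings,
    options = list(window_length = window_length, cumulative = cumulative,
                   directed = directed, scenarios = scenarios,
                   focal_convention = focal_convention)),
    class = "game_evaluation")
}

#' @export
print.game_evaluation <- function(x, ...) {
  cat("Game collaboration evaluation\n")
  cat(sprintf("  actors: %d, exchanges: %d\n", x$n_actors, x$total_exchanges))
  cat(sprintf("  overall DEN = %.4f (%d/%d ties)\n",
              x$overall$den$density, x$overall$den$actual_ties,
              x$overall$den$possible_ties))
  if (!is.null(x$overall$div))
    cat(sprintf("  overall DIV = %.4f (H = %.4f / log(%d) = %.4f)\n",
                x$overall$div$div, x$overall$div$entropy,
                as.integer(x$overall$div$possible_ties),
                x$overall$div$max_entropy))
  for (sc in names(x$per_scenario)) {
    p <- x$per_scenario[[sc]]
    cat(sprintf("  scenario %s: DEN = %.4f%s\n", dQuote(sc), p$den$density,
                if (!is.null(p$div)) sprintf(", DIV = %.4f", p$div$div)
                else ", DIV undefined (silent)"))
  }
  cat(sprintf("  focal comparison (%s): %d focal ties vs %d possible\n",
              x$focal$convention, x$focal$focal_ties, x$focal$all_ties))
  if (!is.null(x$snapshots)) {
    cat(sprintf("  %d snapshot window(s) of %g round(s)%s\n",
                nrow(x$snapshots), attr(x$snapshots, "window_length"),
                if (isTRUE(attr(x$snapshots, "cumulative")))
                  " (cumulative)" else ""))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
summary.game_evaluation <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$snapshots)) {
    cat("\nSnapshots:\n")
    print(as.data.frame(object$snapshots), row.names = FALSE)
  }
  invisible(object)
}

#' Write an evaluation report as canonical JSON
#'
#' The JSON rendering is deterministic: fixed key order and numbers at 12
#' significant digits, so identical inputs give byte-identical files.
#'
#' @param report A [evaluate_game()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "game_evaluation"))
  den_list <- function(d) list(actual_ties = d$actual_ties,
                               possible_ties = d$possible_ties,
                               density = d$density)
  div_list <- function(d) if (is.null(d)) NULL else
    list(entropy = d$entropy, max_entropy = d$max_entropy, div = d$div,
         possible_ties = d$possible_ties, total_weight = d$total_weight)
  out <- list(
    n_actors = report$n_actors,
    total_exchanges = report$total_exchanges,
    options = report$options,
    overall = list(den = den_list(report$overall$den),
                   div = div_list(report$overall$div)),
    per_scenario = lapply(report$per_scenario, function(p)
      list(den = den_list(p$den), div = div_list(p$div),
           role_pairs = list(roles = p$role_pairs$roles,
                             counts = p$role_pairs$counts))),
    snapshots = if (is.null(report$snapshots)) NULL else
      as.data.frame(report$snapshots),
    focal = list(n = report$focal$n, focal_ties = report$focal$focal_ties,
                 all_ties = report$focal$all_ties,
                 convention = report$focal$convention),
    warnings = report$warnings)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = 12,
                           null = "null", na = "null", dataframe = "rows")
  writeLines(json, path)
  invisible(path)
}
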