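#' Construct a tie matrix
#'
#' A tie matrix holds the cumulative communication-exchange counts between
#' every ordered pair of actors. The diagonal is identically zero: the
#' measures here exclude self-to-self ties. An undirected matrix is
#' symmetric, each cell carrying the summed exchanges of both directions.
#'
#' @param weights Square numeric matrix of nonnegative integer exchange
#'   counts with zero diagonal; row/column order defines the actor order.
#' @param actors Character vector of actor IDs (defaults to the dimnames of
#'   `weights`).
#' @param directed Logical; if `FALSE` (default), `weights` must be
#'   symmetric.
#' @param dropped_self Count of self-exchange records discarded while
#'   building the matrix (bookkeeping from [build_tie_matrix()]).
#' @return An object of class `tie_matrix`: a list with elements `actors`,
#'   `weights`, `directed`, `dropped_self`.
#' @seealso [build_tie_matrix()] to tabulate one from an interaction log.
#' @export
tie_matrix <- function(weights, actors = rownames(weights), directed = FALSE,
                       dropped_self = 0L) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("weights must be a square matrix", call. = FALSE)
  if (is.null(actors)) actors <- paste0("actor", seq_len(nrow(weights)))
  actors <- as.character(actors)
  if (length(actors) != nrow(weights) || anyDuplicated(actors))
    stop("actors must be ", nrow(weights), " unique IDs", call. = FALSE)
  if (anyNA(weights) || any(weights < 0))
    stop("exchange counts must be nonnegative", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("diagonal must be zero: self-to-self ties are excluded",
         call. = FALSE)
  if (!directed && !isTRUE(all.equal(weights, t(weights),
                                     check.attributes = FALSE)))
    stop("undirected tie matrix must be symmetric", call. = FALSE)
  dimnames(weights) <- list(actors, actors)
  structure(list(actors = actors, weights = weights,
                 directed = isTRUE(directed),
                 dropped_self = as.integer(dropped_self)),
            class = "tie_matrix")
}

#' Tabulate a tie matrix from an interaction log
#'
#' Aggregates the time-stamped sender-to-receiver exchange records of an
#' interaction log into an actor-by-actor count matrix, optionally restricted
#' to a half-open time window and/or one scenario. Actor order is the roster
#' order, so matrices built from the same roster are directly comparable.
#' Self-exchanges (sender equal to receiver) are dropped, not errors; the
#' number discarded is kept in the result and reported as a warning.
#'
#' @param log An interaction log `data.frame` with columns
#'   `time, scenario, sender, receiver, count` (see [read_interaction_log()]
#'   or [simulate_game()]).
#' @param roster An [actor_roster()] covering every sender and receiver.
#' @param window Optional numeric length-2 vector `c(start, end)`; records
#'   with `start <= time < end` are kept (half-open, so consecutive windows
#'   partition a log with no double counting).
#' @param scenario Optional scenario label to filter on.
#' @param directed Logical; if `FALSE` (default) the two directions of each
#'   pair are summed into a symmetric matrix.
#' @return A [tie_matrix()] over all roster actors (absent actors get zero
#'   rows/columns).
#' @export
#' @examples
#' log <- data.frame(time = c(1, 1), scenario = "s1",
#'                   sender = c("a", "b"), receiver = c("b", "a"),
#'                   count = c(2, 1))
#' ros <- actor_roster(c("a", "b"), c("patient", "physician"))
#' build_tie_matrix(log, ros, directed = TRUE)$weights
build_tie_matrix <- function(log, roster, window = NULL, scenario = NULL,
                             directed = FALSE) {
  roster <- as_roster(roster)
  if (nrow(roster) == 0) stop("empty roster", call. = FALSE)
  log <- as_interaction_log(log)
  unknown <- setdiff(unique(c(log$sender, log$receiver)), roster$actor_id)
  if (length(unknown))
    stop("log contains actors missing from the roster: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  if (!is.null(window)) {
    if (length(window) != 2 || !(window[1] < window[2]))
      stop("window must be c(start, end) with start < end", call. = FALSE)
    log <- log[log$time >= window[1] & log$time < window[2], , drop = FALSE]
  }
  if (!is.null(scenario))
    log <- log[log$scenario %in% scenario, , drop = FALSE]
  self <- log$sender == log$receiver
  n_self <- if (nrow(log)) sum(self) else 0L
  if (n_self > 0) {
    warning("dropped ", n_self, " self-exchange record(s)", call. = FALSE)
    log <- log[!self, , drop = FALSE]
  }
  actors <- roster$actor_id
  w <- matrix(0, length(actors), length(actors),
              dimnames = list(actors, actors))
  if (nrow(log)) {
    idx <- cbind(match(log$sender, actors), match(log$receiver, actors))
    agg <- stats::aggregate(log$count,
                            by = list(i = idx[, 1], j = idx[, 2]), FUN = sum)
    w[cbind(agg$i, agg$j)] <- agg$x
  }
  if (!directed) w <- w + t(w)
  tie_matrix(w, actors, directed = directed, dropped_self = n_self)
}

#' @export
print.tie_matrix <- function(x, ...) {
  cat(sprintf("Tie matrix: %d actors, %s, total exchanges %s\n",
              length(x$actors),
              if (x$directed) "directed" else "undirected",
              format(total_weight(x))))
  if (x$dropped_self > 0)
    cat(sprintf("  (%d self-exchange record(s) dropped)\n", x$dropped_self))
  print(x$weights, ...)
  invisible(x)
}

#' @export
as.matrix.tie_matrix <- function(x, ...) x$weights

# Total exchange count. For an undirected matrix every exchange sits in two
# symmetric cells, so only the upper triangle is summed.
total_weight <- function(m) {
  if (m$directed) sum(m$weights) else sum(m$weights[upper.tri(m$weights)])
}

#' Export a tie matrix
#'
#' `write_tie_matrix()` writes the dense matrix as CSV with actor IDs as row
#' and column labels. `tie_edge_list()` returns (and optionally writes) a
#' `source,target,weight` edge list containing the nonzero ties, suitable
#' for conversion to GraphML or import into graph tools; for an undirected
#' matrix each pair appears once, in actor order.
#'
#' @param m A [tie_matrix()].
#' @param path Output path (for `tie_edge_list()`, optional).
#' @return `write_tie_matrix()` returns `path` invisibly; `tie_edge_list()`
#'   returns the edge-list `data.frame`.
#' @export
write_tie_matrix <- function(m, path) {
  stopifnot(inherits(m, "tie_matrix"))
  utils::write.csv(as.data.frame(m$weights), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_tie_matrix
#' @export
tie_edge_list <- function(m, path = NULL) {
  stopifnot(inherits(m, "tie_matrix"))
  w <- m$weights
  keep <- if (m$directed) w > 0 else upper.tri(w) & w > 0
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(source = m$actors[idx[, 1]],
                    target = m$actors[idx[, 2]],
                    weight = w[idx], stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
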