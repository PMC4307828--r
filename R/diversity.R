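#' Exchange distribution over all possible actor pairs
#'
#' Converts a tie matrix into the probability distribution that network
#' diversity is computed on: the support is every possible pair of actors
#' (unordered for an undirected matrix, ordered for a directed one),
#' zero-weight pairs included, and each pair's probability is its exchange
#' count divided by the total exchange count W.
#'
#' @param m A [tie_matrix()] with at least 2 actors and total weight W >= 1.
#' @return An object of class `pair_distribution`: a `data.frame` with
#'   columns `from`, `to`, `weight`, `prob` (one row per possible pair, in
#'   actor order) and attributes `total_weight` and `directed`.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 4; w[1, 3] <- w[3, 1] <- 1
#' pair_distribution(tie_matrix(w, c("a", "b", "c")))
pair_distribution <- function(m) {
  stopifnot(inherits(m, "tie_matrix"))
  if (length(m$actors) < 2)
    stop("need at least 2 actors", call. = FALSE)
  W <- total_weight(m)
  if (W < 1)
    stop("no interactions: the network is silent (total weight 0), ",
         "so the exchange distribution is undefined", call. = FALSE)
  keep <- if (m$directed) !diag(TRUE, length(m$actors))
          else upper.tri(m$weights)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(from = m$actors[idx[, 1]], to = m$actors[idx[, 2]],
                    weight = m$weights[idx], stringsAsFactors = FALSE)
  out$prob <- out$weight / W
  attr(out, "total_weight") <- W
  attr(out, "directed") <- m$directed
  class(out) <- c("pair_distribution", "data.frame")
  out
}

#' Shannon entropy of an exchange distribution
#'
#' Computes \eqn{H = -\sum_i p_i \log p_i} with the usual convention
#' \eqn{0 \log 0 = 0}. Entropy is maximal, \eqn{\log} of the number of
#' possible pairs, when exchanges are spread perfectly evenly, and zero when
#' all weight sits on one pair.
#'
#' @param p A [pair_distribution()] or a numeric probability vector summing
#'   to 1.
#' @param base Base of the logarithm; natural log (nats) by default. The
#'   normalized diversity ratio is base-invariant.
#' @return Nonnegative entropy value.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5))        # log(2)
#' shannon_entropy(rep(1 / 45, 45))    # log(45)
shannon_entropy <- function(p, base = exp(1)) {
  if (inherits(p, "pair_distribution")) p <- p$prob
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0))
    stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Network diversity
#'
#' Diversity (DIV) measures whether the repeated communication exchanges of
#' a network are concentrated among a small group of actors or evenly
#' distributed among all of them: the Shannon entropy of the exchange
#' distribution over all possible pairs ([pair_distribution()]), normalized
#' by its maximum \eqn{\log PT}. DIV is 1 when every possible pair carries
#' equal weight (perfectly even) and 0 when all exchanges sit on a single
#' pair; unlike density it keeps responding as connected pairs trade
#' repeated exchanges.
#'
#' @param m A [tie_matrix()] with total weight >= 1 and at least 2 possible
#'   pairs (3+ actors when undirected), so the normalization
#'   \eqn{\log PT > 0}.
#' @return An object of class `diversity_result`: list with `entropy` (nats),
#'   `max_entropy` (\eqn{\log PT}), `div` (their ratio, in \[0, 1\]),
#'   `possible_ties`, `total_weight`, `directed`.
#' @export
#' @examples
#' # 10 actors, one exchange on each of the 45 pairs: perfectly even
#' w <- matrix(1, 10, 10); diag(w) <- 0
#' network_diversity(tie_matrix(w, paste0("p", 1:10)))$div  # 1
network_diversity <- function(m) {
  stopifnot(inherits(m, "tie_matrix"))
  pt <- possible_ties(length(m$actors), m$directed)
  if (pt < 2)
    stop("diversity is undefined when only one pair is possible ",
         "(log(PT) = 0); need at least ",
         if (m$directed) "2 actors (directed)" else "3 actors (undirected)",
         call. = FALSE)
  p <- pair_distribution(m)
  H <- shannon_entropy(p)
  structure(list(entropy = H, max_entropy = log(pt), div = H / log(pt),
                 possible_ties = pt,
                 total_weight = attr(p, "total_weight"),
                 directed = m$directed),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf(
    "Network diversity (%s): H = %.4f nats, max = log(%d) = %.4f, DIV = %.4f\n",
    if (x$directed) "directed" else "undirected",
    x$entropy, as.integer(x$possible_ties), x$max_entropy, x$div))
  invisible(x)
}

#' Aggregate exchanges by role pair
#'
#' Answers collaboration-cluster questions — do certain roles tend to
#' collaborate more often in specific scenarios (for example insurance
#' companies and the state government while building the insurance
#' marketplace)? Exchanges are summed by unordered role pair; within-role
#' exchanges (patient with patient) land on the diagonal, so the grand total
#' over distinct role pairs conserves the log's exchange total
#' (self-exchanges excluded).
#'
#' @param log Interaction log `data.frame` (columns
#'   `time, scenario, sender, receiver, count`).
#' @param roster An [actor_roster()] covering the log's actors.
#' @param scenario Optional scenario label to filter on; an unknown label is
#'   an error listing the scenarios present.
#' @return An object of class `role_pair_matrix`: list with `roles` (ordered
#'   labels) and `counts` (symmetric role-by-role matrix of exchange
#'   totals), plus the `scenario` filter used.
#' @export
role_pair_counts <- function(log, roster, scenario = NULL) {
  roster <- as_roster(roster)
  log <- as_interaction_log(log)
  unknown <- setdiff(unique(c(log$sender, log$receiver)), roster$actor_id)
  if (length(unknown))
    stop("log contains actors missing from the roster: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  if (!is.null(scenario)) {
    known <- unique(log$scenario)
    if (!scenario %in% known)
      stop("unknown scenario ", dQuote(scenario), "; scenarios present: ",
           paste(sort(known), collapse = ", "), call. = FALSE)
    log <- log[log$scenario == scenario, , drop = FALSE]
  }
  log <- log[log$sender != log$receiver, , drop = FALSE]
  roles <- attr(roster, "roles")
  if (is.null(roles)) roles <- sort(unique(roster$role))
  counts <- matrix(0, length(roles), length(roles),
                   dimnames = list(roles, roles))
  if (nrow(log)) {
    r1 <- roster$role[match(log$sender, roster$actor_id)]
    r2 <- roster$role[match(log$receiver, roster$actor_id)]
    i <- match(r1, roles); j <- match(r2, roles)
    lo <- pmin(i, j); hi <- pmax(i, j)
    agg <- stats::aggregate(log$count, by = list(lo = lo, hi = hi), FUN = sum)
    for (k in seq_len(nrow(agg))) {
      counts[agg$lo[k], agg$hi[k]] <- counts[agg$lo[k], agg$hi[k]] + agg$x[k]
      if (agg$lo[k] != agg$hi[k])
        counts[agg$hi[k], agg$lo[k]] <- counts[agg$lo[k], agg$hi[k]]
    }
  }
  structure(list(roles = roles, counts = counts, scenario = scenario),
            class = "role_pair_matrix")
}

#' @export
print.role_pair_matrix <- function(x, ...) {
  cat("Role-pair exchange totals",
      if (!is.null(x$scenario)) paste0(" (scenario ", dQuote(x$scenario), ")"),
      ":\n", sep = "")
  print(x$counts, ...)
  invisible(x)
}

#' Serialize diversity results and role-pair matrices
#'
#' `write_role_pair_csv()` writes the labeled role-by-role count matrix as
#' CSV; `diversity_json()` / `role_pair_json()` return compact JSON strings.
#'
#' @param x A `role_pair_matrix` or `diversity_result`.
#' @param path Output path for the CSV.
#' @export
write_role_pair_csv <- function(x, path) {
  stopifnot(inherits(x, "role_pair_matrix"))
  utils::write.csv(as.data.frame(x$counts), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_role_pair_csv
#' @export
diversity_json <- function(x) {
  stopifnot(inherits(x, "diversity_result"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = 12)
}

#' @rdname write_role_pair_csv
#' @export
role_pair_json <- function(x) {
  stopifnot(inherits(x, "role_pair_matrix"))
  jsonlite::toJSON(list(roles = x$roles, scenario = x$scenario,
                        counts = x$counts),
                   auto_unbox = TRUE, digits = 12, null = "null")
}
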