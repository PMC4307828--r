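#' Number of possible communication ties
#'
#' With `n` actors and self-ties excluded, a nondirectional network has
#' \eqn{PT = n(n-1)/2} possible ties (the upper nondiagonal cells of the
#' n-by-n matrix) and a directional network has \eqn{PT = n(n-1)} (all
#' nondiagonal cells).
#'
#' @param n Integer actor count, at least 2.
#' @param directed Logical; count ordered (`TRUE`) or unordered (`FALSE`,
#'   default) pairs.
#' @return The possible-tie count as a number.
#' @export
#' @examples
#' possible_ties(4)              # 6
#' possible_ties(4, directed = TRUE)  # 12
#' possible_ties(10)             # 45
possible_ties <- function(n, directed = FALSE) {
  if (length(n) != 1 || !is.numeric(n) || is.na(n) || n != round(n))
    stop("actor count must be a single integer, got ", deparse(substitute(n)),
         " = ", paste(format(n), collapse = ","), call. = FALSE)
  if (n < 2)
    stop("a network needs at least 2 actors, got n = ", n, call. = FALSE)
  n <- as.numeric(n)
  if (directed) n * (n - 1) else n * (n - 1) / 2
}

#' Network density
#'
#' Density (DEN) indicates how fully the potential connectivity of a network
#' is actually realized: the number of actor pairs with at least one
#' communication exchange, divided by the number of possible ties. A tie is
#' present as soon as the cumulative exchange count of the pair is 1 or more;
#' repeated exchanges do not increase density (see [network_diversity()] for
#' the measure that is sensitive to them).
#'
#' @param m A [tie_matrix()] with at least 2 actors.
#' @return An object of class `density_result`: list with `actual_ties`,
#'   `possible_ties`, `density` (their exact ratio, in \[0, 1\]), `directed`
#'   and `n_actors`.
#' @export
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2:4] <- 1; w[2, 3] <- 1; w[3, 4] <- 1; w[4, 1] <- 1
#' network_density(tie_matrix(w, letters[1:4], directed = TRUE))  # 6/12 = 0.5
network_density <- function(m) {
  stopifnot(inherits(m, "tie_matrix"))
  n <- length(m$actors)
  if (n < 2)
    stop("density needs at least 2 actors, got ", n, call. = FALSE)
  present <- m$weights >= 1
  actual <- if (m$directed) sum(present) else sum(present[upper.tri(present)])
  pt <- possible_ties(n, m$directed)
  structure(list(actual_ties = as.integer(actual),
                 possible_ties = pt,
                 density = actual / pt,
                 directed = m$directed,
                 n_actors = n),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Network density (%s, N = %d): DEN = %d / %d = %.4g\n",
              if (x$directed) "directed" else "undirected",
              x$n_actors, x$actual_ties, x$possible_ties, x$density))
  invisible(x)
}

#' Focal-organization versus whole-network tie comparison
#'
#' Compares the number of ties that involve the focal organization (growing
#' linearly in network size) with the number of all possible nondirectional
#' ties (growing as \eqn{n(n-1)/2}): the whole network offers far more
#' peer-to-peer exchange opportunities than the focal organization's own
#' dyads, which is the structural argument for enrolling many players.
#'
#' Two conventions are available. The `"printed"` convention reports
#' `focal_ties = n` and `all_ties = n(n-1)/2` — the values conventionally
#' tabulated for this comparison (at `n = 10`: 10 vs 45; at `n = 100`:
#' 100 vs 4950). It is internally inconsistent for small `n`: an actor in an
#' n-actor network has only `n - 1` dyads, so the `"self_consistent"`
#' convention reports `focal_ties = n - 1` with the same `all_ties`. The
#' convention used is recorded in the result.
#'
#' @param n Integer network size, at least 1.
#' @param convention `"printed"` (default) or `"self_consistent"`.
#' @return An object of class `focal_comparison`: list with `n`,
#'   `focal_ties`, `all_ties`, `convention` and a `note` describing the
#'   convention.
#' @export
#' @examples
#' focal_vs_all(10)    # 10 vs 45
#' focal_vs_all(100)   # 100 vs 4950
#' focal_vs_all(10, convention = "self_consistent")  # 9 vs 45
focal_vs_all <- function(n, convention = c("printed", "self_consistent")) {
  convention <- match.arg(convention)
  if (length(n) != 1 || !is.numeric(n) || is.na(n) || n != round(n) || n < 1)
    stop("network size must be a single integer >= 1, got ",
         paste(format(n), collapse = ","), call. = FALSE)
  n <- as.numeric(n)
  focal <- if (convention == "printed") n else n - 1
  note <- if (convention == "printed")
    paste0("printed convention: focal_ties = n; inconsistent with the ",
           "pair count for small n (an actor has only n - 1 dyads)")
  else
    "self-consistent convention: focal_ties = n - 1 dyads of the focal actor"
  structure(list(n = n, focal_ties = focal, all_ties = n * (n - 1) / 2,
                 convention = convention, note = note),
            class = "focal_comparison")
}

#' @export
print.focal_comparison <- function(x, ...) {
  cat(sprintf(
    "Focal vs whole network (N = %d, %s convention): %d ties involve the focal organization, %d possible ties in all\n",
    x$n, x$convention, x$focal_ties, x$all_ties))
  invisible(x)
}
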