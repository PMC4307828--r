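#' Build the player roster implied by a game configuration
#'
#' Player IDs are `<role>_<k>` in role order; the focal flag goes to
#' `config$focal_actor` if set, otherwise to the first player of the first
#' role.
#'
#' @param config A [game_config()].
#' @return An [actor_roster()].
#' @export
config_roster <- function(config) {
  stopifnot(inherits(config, "game_config"))
  ids <- unlist(lapply(names(config$roles), function(r)
    paste0(r, "_", seq_len(config$roles[[r]]))), use.names = FALSE)
  roles <- rep(names(config$roles), times = config$roles)
  focal <- config$focal_actor %||% ids[1]
  if (!focal %in% ids)
    stop("focal_actor ", dQuote(focal), " is not a generated player ID",
         call. = FALSE)
  actor_roster(ids, roles, is_focal = ids == focal,
               roles = union(default_roles(), names(config$roles)))
}

#' Draw the pair-level interaction propensity vector
#'
#' The simulator's model of "who talks to whom": a symmetric-Dirichlet
#' vector with concentration `alpha` over all unordered actor pairs (drawn
#' via independent Gamma(alpha) variates, normalized), reweighted by the
#' affinity of each pair's role pair and renormalized. Small `alpha`
#' concentrates propensity on few pairs (yielding low network diversity
#' downstream); large `alpha` spreads it evenly. A zero affinity entry
#' silences the corresponding role pairs entirely.
#'
#' @param config A [game_config()] (supplies `concentration` and the
#'   baseline affinity).
#' @param roster Roster of players; defaults to [config_roster()].
#' @param affinity Optional affinity override (e.g. a per-scenario matrix).
#' @return Numeric vector summing to 1, one entry per unordered actor pair
#'   in roster order, named `"a|b"`.
#' @export
sample_pair_propensities <- function(config, roster = config_roster(config),
                                     affinity = config$affinity) {
  stopifnot(inherits(config, "game_config"))
  roster <- as_roster(roster, require_n = 2L)
  n <- nrow(roster)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  aff <- affinity[cbind(roster$role[idx[, 1]], roster$role[idx[, 2]])]
  g <- stats::rgamma(nrow(idx), shape = config$concentration, rate = 1)
  w <- g * aff
  if (sum(w) <= 0) {
    if (all(aff == 0))
      stop("degenerate configuration: affinity masks every actor pair",
           call. = FALSE)
    # numerical underflow of every gamma draw at tiny alpha: put all mass
    # on one admissible pair chosen uniformly
    w[sample(which(aff > 0), 1)] <- 1
  }
  stats::setNames(w / sum(w),
                  paste(roster$actor_id[idx[, 1]], roster$actor_id[idx[, 2]],
                        sep = "|"))
}

#' Draw one environmental event outcome for a role
#'
#' Each round the game generates random but plausible environmental
#' conditions per role (market share shifting, patient status changing, ...)
#' from the role's categorical event model; the outcome's fixed utility
#' feeds the role players' task scores.
#'
#' @param config A [game_config()].
#' @param role Role label with an event model in the config.
#' @return List with `outcome` (label) and `utility` (number).
#' @export
sample_environment <- function(config, role) {
  stopifnot(inherits(config, "game_config"))
  em <- config$event_model[[role]]
  if (is.null(em))
    stop("role ", dQuote(role), " has no event model; configured roles: ",
         paste(names(config$event_model), collapse = ", "), call. = FALSE)
  k <- length(em$outcomes)
  i <- if (k == 1) 1L else sample.int(k, 1L, prob = em$probs)
  list(outcome = em$outcomes[i], utility = em$utilities[i])
}

#' Simulate a multi-role policy game
#'
#' Plays the configured game and records everything a real deployment's
#' backend would: the interaction log, per-player scores and the
#' environmental-event trace. The run is fully reproducible from the config
#' seed; the global RNG state is left untouched.
#'
#' Per scenario, the pair propensity vector is drawn once (with the
#' scenario's affinity, if given) via [sample_pair_propensities()]. Per
#' round, the total exchange count is Poisson(`exchanges_per_round`), the
#' exchanges are allocated to pairs multinomially by the propensity vector,
#' each exchange takes a uniformly random direction, and one environmental
#' event per role is drawn via [sample_environment()]. The RNG stream is
#' advanced in that fixed order (scenario propensities, then per round:
#' volume, allocation, directions, events).
#'
#' Scores, per player and scenario: `task_score` sums the utilities of the
#' player's role events; `engagement_score` counts the exchanges the player
#' participated in (as sender or receiver); `total = task_score +
#' engagement_weight * engagement_score`.
#'
#' @param config A validated [game_config()].
#' @return An object of class `game_run`: list with `log` (data.frame
#'   `time, scenario, sender, receiver, count`; `time` is a global round
#'   index starting at 1), `scores` (data.frame `player, role, scenario,
#'   task_score, engagement_score, total`), `events` (data.frame
#'   `time, scenario, role, outcome, utility`), `roster`, `config`.
#' @export
#' @examples
#' run <- simulate_game(aca_game_config(seed = 7))
#' network_density(build_tie_matrix(run$log, run$roster))
simulate_game <- function(config) {
  stopifnot(inherits(config, "game_config"))
  validate_game_config(config)
  roster <- config_roster(config)
  if (nrow(roster) < 2)
    stop("the game needs at least 2 players", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- nrow(roster)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  roles <- names(config$roles)

  logs <- list(); events <- list()
  engagement <- new.env(parent = emptyenv())
  task <- new.env(parent = emptyenv())
  bump <- function(env, key, by) assign(key, (get0(key, envir = env) %||% 0) + by,
                                        envir = env)
  t_global <- 0L
  for (sc in config$scenarios) {
    prop <- sample_pair_propensities(config, roster,
                                     affinity = sc$affinity %||% config$affinity)
    for (r in seq_len(sc$rounds)) {
      t_global <- t_global + 1L
      n_ex <- stats::rpois(1, config$exchanges_per_round)
      if (n_ex > 0) {
        alloc <- as.vector(stats::rmultinom(1, n_ex, prob = prop))
        hot <- which(alloc > 0)
        for (k in hot) {
          i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
          fwd <- stats::rbinom(1, alloc[k], 0.5)
          bwd <- alloc[k] - fwd
          a <- roster$actor_id[i]; b <- roster$actor_id[j]
          if (fwd > 0)
            logs[[length(logs) + 1L]] <- list(t_global, sc$label, a, b, fwd)
          if (bwd > 0)
            logs[[length(logs) + 1L]] <- list(t_global, sc$label, b, a, bwd)
          bump(engagement, paste(a, sc$label, sep = "\r"), alloc[k])
          bump(engagement, paste(b, sc$label, sep = "\r"), alloc[k])
        }
      }
      for (role in roles) {
        ev <- sample_environment(config, role)
        events[[length(events) + 1L]] <-
          list(t_global, sc$label, role, ev$outcome, ev$utility)
        bump(task, paste(role, sc$label, sep = "\r"), ev$utility)
      }
    }
  }

  log <- if (length(logs)) {
    data.frame(time = vapply(logs, `[[`, integer(1), 1),
               scenario = vapply(logs, `[[`, character(1), 2),
               sender = vapply(logs, `[[`, character(1), 3),
               receiver = vapply(logs, `[[`, character(1), 4),
               count = vapply(logs, function(x) as.integer(x[[5]]), integer(1)),
               stringsAsFactors = FALSE)
  } else empty_log()
  evts <- data.frame(
    time = vapply(events, `[[`, integer(1), 1),
    scenario = vapply(events, `[[`, character(1), 2),
    role = vapply(events, `[[`, character(1), 3),
    outcome = vapply(events, `[[`, character(1), 4),
    utility = vapply(events, function(x) as.numeric(x[[5]]), numeric(1)),
    stringsAsFactors = FALSE)

  scen_labels <- vapply(config$scenarios, `[[`, character(1), "label")
  grid <- expand.grid(player = roster$actor_id, scenario = scen_labels,
                      stringsAsFactors = FALSE)
  grid$role <- roster$role[match(grid$player, roster$actor_id)]
  grid$task_score <- mapply(function(role, sc)
    get0(paste(role, sc, sep = "\r"), envir = task) %||% 0,
    grid$role, grid$scenario)
  grid$engagement_score <- mapply(function(p, sc)
    get0(paste(p, sc, sep = "\r"), envir = engagement) %||% 0,
    grid$player, grid$scenario)
  grid$total <- grid$task_score +
    config$engagement_weight * grid$engagement_score
  scores <- grid[, c("player", "role", "scenario", "task_score",
                     "engagement_score", "total")]

  structure(list(log = log, scores = scores, events = evts,
                 roster = roster, config = config),
            class = "game_run")
}

#' @export
print.game_run <- function(x, ...) {
  cat(sprintf(
    "Simulated game run: %d players, %d scenarios, %d log records (%d exchanges), seed %d\n",
    nrow(x$roster), length(x$config$scenarios), nrow(x$log),
    sum(x$log$count), x$config$seed))
  invisible(x)
}

empty_log <- function() {
  data.frame(time = integer(), scenario = character(), sender = character(),
             receiver = character(), count = integer(),
             stringsAsFactors = FALSE)
}
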