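#' Construct a game configuration
#'
#' A `game_config` describes a multi-role policy game to be played by the
#' simulator: which roles exist and how many players each has, the scenario
#' sequence, the role-pair affinity structure governing who tends to talk to
#' whom, the Dirichlet concentration controlling how evenly exchange
#' propensity is spread over actor pairs, the expected exchange volume per
#' round, the per-role environmental-event models used for scoring, and the
#' RNG seed.
#'
#' @param roles Named integer vector: players per role (all >= 1). Names are
#'   the role labels.
#' @param scenarios List of scenario specs, each a list with `label`
#'   (unique string) and `rounds` (integer >= 1), optionally `affinity` (a
#'   per-scenario override of the affinity matrix).
#' @param affinity Symmetric nonnegative role-by-role matrix of interaction
#'   propensity multipliers (dimnames = role labels); at least one entry
#'   positive. Default: all ones (no role preference).
#' @param concentration Dirichlet concentration alpha > 0. Small values
#'   concentrate exchange propensity on few pairs (low diversity); large
#'   values spread it evenly (high diversity). Default 1.
#' @param exchanges_per_round Expected total exchanges per round,
#'   lambda > 0 of the per-round Poisson draw. Default 30.
#' @param event_model Named list (one entry per role), each a list with
#'   `outcomes` (labels), `probs` (summing to 1) and `utilities` (numeric,
#'   same length). Default: [default_event_model()] for the six standard
#'   roles, a two/three-outcome model per role.
#' @param engagement_weight Weight of the engagement count in the total
#'   score. Default 0.1.
#' @param focal_actor Actor ID flagged focal in the emitted roster; default
#'   the first player of the first role.
#' @param seed Integer RNG seed. Default 1.
#' @return A validated object of class `game_config`.
#' @seealso [aca_game_config()] for the ready-made six-role game,
#'   [simulate_game()] to play it.
#' @export
game_config <- function(roles, scenarios, affinity = NULL,
                        concentration = 1, exchanges_per_round = 30,
                        event_model = NULL, engagement_weight = 0.1,
                        focal_actor = NULL, seed = 1L) {
  role_labels <- names(roles)
  if (is.null(affinity) && !is.null(role_labels)) {
    affinity <- matrix(1, length(roles), length(roles),
                       dimnames = list(role_labels, role_labels))
  }
  if (is.null(event_model) && !is.null(role_labels))
    event_model <- default_event_model(role_labels)
  cfg <- structure(list(roles = roles, scenarios = scenarios,
                        affinity = affinity,
                        concentration = concentration,
                        exchanges_per_round = exchanges_per_round,
                        event_model = event_model,
                        engagement_weight = engagement_weight,
                        focal_actor = focal_actor,
                        seed = as.integer(seed)),
                   class = "game_config")
  validate_game_config(cfg)
  cfg
}

#' Default per-role environmental-event models
#'
#' Each role receives random but plausible environmental outcomes each round
#' (a hospital's market share moving up or down, a patient's health status
#' improving or worsening, ...), each outcome carrying a fixed utility that
#' feeds the role players' task scores. These defaults are a documented toy
#' model, freely overridable in [game_config()].
#'
#' @param roles Role labels to build models for; unknown labels get a
#'   neutral two-outcome model.
#' @return Named list of event models (`outcomes`, `probs`, `utilities`).
#' @export
default_event_model <- function(roles = default_roles()) {
  base <- list(
    federal_government = list(
      outcomes = c("initiative_adopted", "initiative_stalled"),
      probs = c(0.5, 0.5), utilities = c(2, -1)),
    state_government = list(
      outcomes = c("public_support_up", "public_support_down"),
      probs = c(0.6, 0.4), utilities = c(2, -1)),
    hospital = list(
      outcomes = c("market_share_up", "market_share_down"),
      probs = c(0.5, 0.5), utilities = c(2, -1)),
    insurance_company = list(
      outcomes = c("enrollment_up", "enrollment_down"),
      probs = c(0.5, 0.5), utilities = c(2, -1)),
    physician = list(
      outcomes = c("satisfaction_up", "satisfaction_down"),
      probs = c(0.6, 0.4), utilities = c(1, -1)),
    patient = list(
      outcomes = c("status_improved", "status_unchanged", "status_worsened"),
      probs = c(0.4, 0.4, 0.2), utilities = c(2, 0, -1)))
  out <- lapply(roles, function(r) {
    if (!is.null(base[[r]])) base[[r]]
    else list(outcomes = c("favorable", "unfavorable"),
              probs = c(0.5, 0.5), utilities = c(1, -1))
  })
  names(out) <- roles
  out
}

#' Ready-made six-role health-policy game configuration
#'
#' The package's reference game: the six stakeholder roles (federal and
#' state government, hospital, insurance company, physician, patient), each
#' played by `players_per_role` players, across two policy scenarios —
#' building the health insurance marketplace and expanding public coverage —
#' of `rounds` rounds each.
#'
#' @param players_per_role Players per role (default 2, i.e. 12 actors).
#' @param rounds Rounds per scenario (default 10).
#' @param concentration,exchanges_per_round,seed Passed to [game_config()].
#' @param marketplace_boost Multiplier applied to the insurance-company /
#'   state-government affinity in the marketplace scenario (default 1, no
#'   boost). Setting it above 1 makes that role pair collaborate more there.
#' @return A `game_config`.
#' @export
#' @examples
#' cfg <- aca_game_config(seed = 42)
#' run <- simulate_game(cfg)
#' head(run$log)
aca_game_config <- function(players_per_role = 2, rounds = 10,
                            concentration = 1, exchanges_per_round = 30,
                            marketplace_boost = 1, seed = 1L) {
  roles <- stats::setNames(rep(as.integer(players_per_role), 6L),
                           default_roles())
  scen1 <- list(label = "marketplace", rounds = as.integer(rounds))
  if (marketplace_boost != 1) {
    aff <- matrix(1, 6, 6, dimnames = list(default_roles(), default_roles()))
    aff["insurance_company", "state_government"] <- marketplace_boost
    aff["state_government", "insurance_company"] <- marketplace_boost
    scen1$affinity <- aff
  }
  game_config(
    roles = roles,
    scenarios = list(scen1,
                     list(label = "medicaid_expansion",
                          rounds = as.integer(rounds))),
    concentration = concentration,
    exchanges_per_round = exchanges_per_round,
    seed = seed)
}

# Validate a game_config, collecting every violation into one error.
validate_game_config <- function(cfg) {
  errs <- character()
  push <- function(msg) errs <<- c(errs, msg)

  if (is.null(names(cfg$roles)) || any(!nzchar(names(cfg$roles))))
    push("roles must be a named vector of players-per-role counts")
  if (!is.numeric(cfg$roles) || any(is.na(cfg$roles)) ||
      any(cfg$roles < 1) || any(cfg$roles != round(cfg$roles)))
    push("players per role must be integers >= 1")
  if (sum(cfg$roles) < 2)
    push("the game needs at least 2 players overall")

  if (!is.list(cfg$scenarios) || !length(cfg$scenarios)) {
    push("scenarios must be a non-empty list")
  } else {
    labs <- vapply(cfg$scenarios, function(s)
      if (is.character(s$label) && length(s$label) == 1) s$label else NA_character_,
      character(1))
    if (anyNA(labs)) push("every scenario needs a single string label")
    if (anyDuplicated(stats::na.omit(labs)))
      push("scenario labels must be unique")
    for (s in cfg$scenarios) {
      if (is.null(s$rounds) || !is.numeric(s$rounds) || length(s$rounds) != 1 ||
          is.na(s$rounds) || s$rounds < 1 || s$rounds != round(s$rounds))
        push(paste0("scenario ", dQuote(s$label %||% "?"),
                    ": rounds must be an integer >= 1"))
      if (!is.null(s$affinity) &&
          !is.null(bad <- check_affinity(s$affinity, names(cfg$roles))))
        push(paste0("scenario ", dQuote(s$label %||% "?"), ": ", bad))
    }
  }

  if (!is.null(bad <- check_affinity(cfg$affinity, names(cfg$roles))))
    push(bad)

  if (!is.numeric(cfg$concentration) || length(cfg$concentration) != 1 ||
      is.na(cfg$concentration) || cfg$concentration <= 0)
    push("concentration (Dirichlet alpha) must be a single value > 0")
  if (!is.numeric(cfg$exchanges_per_round) ||
      length(cfg$exchanges_per_round) != 1 ||
      is.na(cfg$exchanges_per_round) || cfg$exchanges_per_round <= 0)
    push("exchanges_per_round (lambda) must be a single value > 0")

  for (r in names(cfg$roles)) {
    em <- cfg$event_model[[r]]
    if (is.null(em)) { push(paste0("role ", dQuote(r), " has no event model")); next }
    k <- length(em$outcomes)
    if (k < 1 || length(em$probs) != k || length(em$utilities) != k)
      push(paste0("role ", dQuote(r),
                  ": outcomes, probs and utilities must have equal length >= 1"))
    else if (any(em$probs < 0) || abs(sum(em$probs) - 1) > 1e-8)
      push(paste0("role ", dQuote(r), ": event probabilities must be ",
                  "nonnegative and sum to 1"))
  }

  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    push("seed must be a single integer")

  if (length(errs))
    stop("invalid game configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

check_affinity <- function(aff, role_labels) {
  if (is.null(aff)) return("affinity matrix is missing")
  if (!is.matrix(aff) || nrow(aff) != length(role_labels) ||
      ncol(aff) != length(role_labels))
    return("affinity must be a square role-by-role matrix")
  if (!identical(rownames(aff), role_labels) ||
      !identical(colnames(aff), role_labels))
    return("affinity dimnames must equal the role labels, in order")
  if (anyNA(aff) || any(aff < 0)) return("affinity entries must be >= 0")
  if (!isTRUE(all.equal(aff, t(aff), check.attributes = FALSE)))
    return("affinity must be symmetric")
  if (all(aff == 0)) return("affinity must have at least one positive entry")
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.game_config <- function(x, ...) {
  cat("Game configuration:\n")
  cat("  roles: ", paste(sprintf("%s x%d", names(x$roles), x$roles),
                         collapse = ", "), "\n", sep = "")
  cat("  scenarios: ",
      paste(vapply(x$scenarios,
                   function(s) sprintf("%s (%d rounds)", s$label, s$rounds),
                   character(1)), collapse = ", "), "\n", sep = "")
  cat(sprintf("  concentration alpha = %g, lambda = %g exchanges/round, seed = %d\n",
              x$concentration, x$exchanges_per_round, x$seed))
  invisible(x)
}

#' Read or write a game configuration file
#'
#' YAML is the canonical on-disk format; JSON is accepted too, detected by
#' extension. Matrices are stored as row-major lists of rows with a `roles`
#' ordering implied by the `roles` field.
#'
#' @param path Path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_game_config()` returns a validated `game_config`;
#'   `write_game_config()` returns `path` invisibly.
#' @export
read_game_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- switch(tolower(tools::file_ext(path)),
                "yaml" = , "yml" = yaml::read_yaml(path),
                "json" = jsonlite::read_json(path, simplifyVector = FALSE),
                stop("unsupported config extension: ", path, call. = FALSE))
  role_labels <- names(raw$roles)
  to_mat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- do.call(rbind, lapply(m, function(row) as.numeric(unlist(row))))
    dimnames(m) <- list(role_labels, role_labels)
    m
  }
  scenarios <- lapply(raw$scenarios, function(s) {
    s$rounds <- as.integer(s$rounds)
    if (!is.null(s$affinity)) s$affinity <- to_mat(s$affinity)
    s
  })
  em <- raw$event_model
  if (!is.null(em))
    em <- lapply(em, function(e)
      list(outcomes = as.character(unlist(e$outcomes)),
           probs = as.numeric(unlist(e$probs)),
           utilities = as.numeric(unlist(e$utilities))))
  game_config(roles = unlist(raw$roles), scenarios = scenarios,
              affinity = to_mat(raw$affinity),
              concentration = raw$concentration %||% 1,
              exchanges_per_round = raw$exchanges_per_round %||% 30,
              event_model = em,
              engagement_weight = raw$engagement_weight %||% 0.1,
              focal_actor = raw$focal_actor,
              seed = raw$seed %||% 1L)
}

#' @rdname read_game_config
#' @param config A `game_config`.
#' @export
write_game_config <- function(config, path) {
  stopifnot(inherits(config, "game_config"))
  from_mat <- function(m) if (is.null(m)) NULL else
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  out <- list(
    roles = as.list(stats::setNames(as.integer(config$roles),
                                    names(config$roles))),
    scenarios = lapply(config$scenarios, function(s) {
      s$affinity <- from_mat(s$affinity); s[!vapply(s, is.null, logical(1))]
    }),
    affinity = from_mat(config$affinity),
    concentration = config$concentration,
    exchanges_per_round = config$exchanges_per_round,
    event_model = config$event_model,
    engagement_weight = config$engagement_weight,
    focal_actor = config$focal_actor,
    seed = config$seed)
  out <- out[!vapply(out, is.null, logical(1))]
  switch(tolower(tools::file_ext(path)),
         "yaml" = , "yml" = yaml::write_yaml(out, path),
         "json" = jsonlite::write_json(out, path, auto_unbox = TRUE,
                                       digits = 12),
         stop("unsupported config extension: ", path, call. = FALSE))
  invisible(path)
}
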