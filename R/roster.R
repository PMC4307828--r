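#' Default stakeholder role set
#'
#' The six stakeholder roles of the built-in health-policy game: the federal
#' government, the state government, the hospital, the insurance company, the
#' physician and the patient. Each role may be played by several players.
#'
#' @return Character vector of six role labels.
#' @export
#' @examples
#' default_roles()
default_roles <- function() {
  c("federal_government", "state_government", "hospital",
    "insurance_company", "physician", "patient")
}

#' Construct an actor roster
#'
#' A roster maps player (actor) IDs to their stakeholder roles and flags at
#' most one actor as the focal organization — the convening actor (for
#' example the agency or college hosting the game) against whose dyadic
#' reach whole-network connectivity is compared.
#'
#' @param actor_id Character vector of unique, non-empty actor IDs.
#' @param role Character vector of role labels, one per actor; every label
#'   must be in `roles`.
#' @param is_focal Logical vector, at most one `TRUE`. Defaults to all
#'   `FALSE`.
#' @param roles Character vector of permitted role labels (the configured
#'   role set). Defaults to [default_roles()] extended by any labels present
#'   in `role`.
#' @return A `data.frame` of class `actor_roster` with columns `actor_id`,
#'   `role`, `is_focal` and attribute `roles` (the role set, in order).
#' @export
#' @examples
#' actor_roster(c("fed1", "pat1"), c("federal_government", "patient"),
#'              is_focal = c(TRUE, FALSE))
actor_roster <- function(actor_id, role, is_focal = NULL, roles = NULL) {
  actor_id <- as.character(actor_id)
  role <- as.character(role)
  if (is.null(is_focal)) is_focal <- rep(FALSE, length(actor_id))
  if (length(role) != length(actor_id) || length(is_focal) != length(actor_id))
    stop("actor_id, role and is_focal must have equal length", call. = FALSE)
  if (any(!nzchar(actor_id)) || anyNA(actor_id))
    stop("actor IDs must be non-empty strings", call. = FALSE)
  if (anyDuplicated(actor_id))
    stop("duplicate actor IDs: ",
         paste(unique(actor_id[duplicated(actor_id)]), collapse = ", "),
         call. = FALSE)
  if (is.null(roles)) roles <- union(default_roles(), role)
  bad <- setdiff(unique(role), roles)
  if (length(bad))
    stop("roles not in the configured role set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  is_focal <- as.logical(is_focal)
  if (sum(is_focal, na.rm = TRUE) > 1)
    stop("at most one actor may be flagged focal", call. = FALSE)
  out <- data.frame(actor_id = actor_id, role = role, is_focal = is_focal,
                    stringsAsFactors = FALSE)
  attr(out, "roles") <- roles
  class(out) <- c("actor_roster", "data.frame")
  out
}

# Coerce/validate roster-like input; networks need >= 2 actors when
# require_n is set.
as_roster <- function(roster, require_n = 0L) {
  if (!inherits(roster, "actor_roster")) {
    if (!is.data.frame(roster) ||
        !all(c("actor_id", "role") %in% names(roster)))
      stop("roster must be an actor_roster or a data.frame with columns ",
           "actor_id and role", call. = FALSE)
    roster <- actor_roster(roster$actor_id, roster$role,
                           if ("is_focal" %in% names(roster)) roster$is_focal)
  }
  if (nrow(roster) < require_n)
    stop("roster has ", nrow(roster), " actors; at least ", require_n,
         " are required", call. = FALSE)
  roster
}

#' Read or write a roster CSV
#'
#' The on-disk format is a CSV with header `actor_id,role,is_focal`.
#'
#' @param path Path to the CSV file.
#' @return `read_roster()` returns an [actor_roster()]; `write_roster()`
#'   returns `path` invisibly.
#' @export
read_roster <- function(path) {
  df <- read_checked_csv(path, c("actor_id", "role", "is_focal"))
  actor_roster(df$actor_id, df$role, as.logical(df$is_focal))
}

#' @rdname read_roster
#' @param roster An [actor_roster()].
#' @export
write_roster <- function(roster, path) {
  roster <- as_roster(roster)
  utils::write.csv(as.data.frame(roster)[, c("actor_id", "role", "is_focal")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
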