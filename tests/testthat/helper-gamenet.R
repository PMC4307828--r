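# Shared fixture builders and independent oracles.

# Small roster of n actors cycling over the six default roles.
tiny_roster <- function(n, focal = FALSE) {
  roles <- rep(default_roles(), length.out = n)
  actor_roster(paste0("p", seq_len(n)), roles,
               is_focal = c(focal, rep(FALSE, n - 1)))
}

# A log data.frame from parallel vectors.
make_log <- function(sender, receiver, count = 1, time = 1, scenario = "s1") {
  data.frame(time = time, scenario = scenario,
             sender = sender, receiver = receiver, count = count,
             stringsAsFactors = FALSE)
}

# Random log over a roster: n_rec records at random rounds/pairs.
random_log <- function(roster, n_rec, rounds = 10, scenarios = "s1") {
  i <- sample.int(nrow(roster), n_rec, replace = TRUE)
  j <- sample.int(nrow(roster) - 1, n_rec, replace = TRUE)
  j <- ifelse(j >= i, j + 1, j)  # j != i
  make_log(roster$actor_id[i], roster$actor_id[j],
           count = sample.int(5, n_rec, replace = TRUE),
           time = sample.int(rounds, n_rec, replace = TRUE),
           scenario = sample(scenarios, n_rec, replace = TRUE))
}

# Independent oracle: entropy by naive direct summation over every term.
entropy_oracle <- function(p) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log(x)
  h
}

# Independent oracle: possible ties by brute-force pair enumeration.
enumerate_pairs <- function(n, directed) {
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!directed && j < i) next
    cnt <- cnt + 1L
  }
  cnt
}

# Random undirected tie matrix over n actors with n_pos weighted pairs.
random_tie_matrix <- function(n, n_pos = NULL) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (is.null(n_pos)) n_pos <- sample.int(nrow(pairs), 1)
  pick <- sample.int(nrow(pairs), n_pos)
  w <- matrix(0, n, n)
  w[pairs[pick, , drop = FALSE]] <- sample.int(10, n_pos, replace = TRUE)
  w <- w + t(w)
  tie_matrix(w, paste0("a", seq_len(n)))
}
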