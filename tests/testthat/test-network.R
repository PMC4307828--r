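test_that("possible_ties matches the closed forms and rejects bad input", {
  expect_identical(possible_ties(4, directed = FALSE), 6)
  expect_identical(possible_ties(4, directed = TRUE), 12)
  expect_identical(possible_ties(2, directed = FALSE), 1)
  expect_identical(possible_ties(100, directed = FALSE), 4950)
  expect_error(possible_ties(1), "at least 2")
  expect_error(possible_ties(3.5), "integer")
  expect_error(possible_ties(c(3, 4)), "single")
})

test_that("possible_ties agrees with brute-force pair enumeration, n = 2..50", {
  for (n in 2:50) {
    expect_equal(possible_ties(n, FALSE), enumerate_pairs(n, FALSE))
    expect_equal(possible_ties(n, TRUE), enumerate_pairs(n, TRUE))
  }
})

test_that("tie matrices are tabulated from logs with both directions handled", {
  ros <- actor_roster(c("a", "b"), c("patient", "physician"))
  log <- make_log(c("a", "b"), c("b", "a"), count = c(2, 1))
  md <- build_tie_matrix(log, ros, directed = TRUE)
  expect_equal(md$weights["a", "b"], 2)
  expect_equal(md$weights["b", "a"], 1)
  mu <- build_tie_matrix(log, ros, directed = FALSE)
  expect_equal(mu$weights["a", "b"], 3)
  expect_equal(mu$weights["b", "a"], 3)
})

test_that("self-exchanges are dropped with a warning, not an error", {
  ros <- actor_roster(c("a", "b"), c("patient", "physician"))
  log <- make_log("a", "a", count = 1)
  expect_warning(m <- build_tie_matrix(log, ros), "1 self-exchange")
  expect_true(all(m$weights == 0))
  expect_equal(m$dropped_self, 1L)
})

test_that("unknown log actors and empty rosters are errors naming the problem", {
  ros <- actor_roster(c("a", "b"), c("patient", "physician"))
  log <- make_log("a", "zzz")
  expect_error(build_tie_matrix(log, ros), "zzz")
  expect_error(build_tie_matrix(log, ros[0, ]), "at least|empty")
})

test_that("window and scenario filters restrict tabulation correctly", {
  ros <- tiny_roster(3)
  log <- make_log(c("p1", "p1", "p2"), c("p2", "p3", "p3"),
                  count = c(1, 2, 4), time = c(1, 5, 9),
                  scenario = c("s1", "s1", "s2"))
  m <- build_tie_matrix(log, ros, window = c(1, 5))
  expect_equal(total_weight(m), 1)
  m <- build_tie_matrix(log, ros, window = c(5, 10))
  expect_equal(total_weight(m), 6)
  m <- build_tie_matrix(log, ros, scenario = "s2")
  expect_equal(total_weight(m), 4)
  # half-open: record at t = 5 belongs to [5, 10) only
  expect_equal(total_weight(build_tie_matrix(log, ros, window = c(1, 5))) +
               total_weight(build_tie_matrix(log, ros, window = c(5, 10))),
               sum(log$count))
  expect_error(build_tie_matrix(log, ros, window = c(5, 5)), "start < end")
})

test_that("density reproduces the 4-actor worked example and the extremes", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[1, 3] <- w[1, 4] <- w[2, 3] <- w[3, 4] <- w[4, 1] <- 1
  d <- network_density(tie_matrix(w, letters[1:4], directed = TRUE))
  expect_equal(d$actual_ties, 6L)
  expect_equal(d$possible_ties, 12)
  expect_equal(d$density, 0.5)

  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_equal(network_density(tie_matrix(full, letters[1:5]))$density, 1)

  zero <- tie_matrix(matrix(0, 6, 6), letters[1:6])
  expect_equal(network_density(zero)$density, 0)
  expect_error(network_density(tie_matrix(matrix(0, 1, 1), "a")), "at least 2")
})

test_that("density is bounded, permutation-invariant, and >= directed density", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    ros <- tiny_roster(n)
    log <- random_log(ros, sample(1:30, 1))
    mu <- build_tie_matrix(log, ros, directed = FALSE)
    md <- build_tie_matrix(log, ros, directed = TRUE)
    du <- network_density(mu)$density
    dd <- network_density(md)$density
    expect_gte(du, 0); expect_lte(du, 1)
    expect_gte(dd, 0); expect_lte(dd, 1)
    # symmetrized density counts each communicating pair once out of half
    # the possible cells, so it can never fall below the directed density
    expect_gte(du, dd)
    # relabeling actors must not change density
    perm <- sample(n)
    m2 <- tie_matrix(mu$weights[perm, perm], mu$actors[perm])
    expect_equal(network_density(m2)$density, du)
  }
})

test_that("focal comparison reproduces the tabulated values and its growth law", {
  fc <- focal_vs_all(10)
  expect_equal(fc$focal_ties, 10)
  expect_equal(fc$all_ties, 45)
  expect_equal(focal_vs_all(100)$focal_ties, 100)
  expect_equal(focal_vs_all(100)$all_ties, 4950)
  expect_equal(focal_vs_all(50)$all_ties, 1225)
  # self-consistent mode: the focal actor has only n - 1 dyads
  sc <- focal_vs_all(10, convention = "self_consistent")
  expect_equal(sc$focal_ties, 9)
  expect_equal(sc$all_ties, 45)
  expect_match(fc$note, "convention")
  # quadratic vs linear growth: all/focal == (n-1)/2 exactly
  for (n in c(2, 10, 50, 100, 1000)) {
    fc <- focal_vs_all(n)
    expect_equal(fc$all_ties / fc$focal_ties, (n - 1) / 2)
  }
  expect_error(focal_vs_all(0), ">= 1")
})
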