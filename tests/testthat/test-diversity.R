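test_that("pair distribution spans all possible pairs and conserves mass", {
  # 10 actors, all 10 exchanges between one pair: one prob 1, 44 zeros
  w <- matrix(0, 10, 10); w[1, 2] <- w[2, 1] <- 10
  p <- pair_distribution(tie_matrix(w, paste0("p", 1:10)))
  expect_equal(nrow(p), 45)
  expect_equal(sum(p$prob == 1), 1)
  expect_equal(sum(p$prob == 0), 44)
  expect_equal(attr(p, "total_weight"), 10)

  u <- matrix(1, 10, 10); diag(u) <- 0
  pu <- pair_distribution(tie_matrix(u, paste0("p", 1:10)))
  expect_equal(pu$prob, rep(1 / 45, 45))

  expect_error(pair_distribution(tie_matrix(matrix(0, 4, 4), letters[1:4])),
               "no interactions")

  set.seed(7)
  for (rep in 1:50) {
    m <- random_tie_matrix(sample(3:10, 1))
    expect_equal(sum(pair_distribution(m)$prob), 1, tolerance = 1e-12)
  }
})

test_that("Shannon entropy matches closed forms and validates its input", {
  expect_equal(shannon_entropy(c(1, rep(0, 9))), 0)
  expect_equal(shannon_entropy(rep(1 / 45, 45)), log(45))
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), log(2))
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(-0.5, 1.5)), "nonnegative")
})

test_that("entropy agrees with a brute-force summation oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:1000) {
    k <- sample(2:40, 1)
    p <- stats::rgamma(k, shape = runif(1, 0.2, 3))
    p[sample(k, sample(0:(k - 1), 1))] <- 0  # include zero entries
    if (sum(p) == 0) p[1] <- 1
    p <- p / sum(p)
    expect_equal(shannon_entropy(p), entropy_oracle(p), tolerance = 1e-12)
  }
})

test_that("diversity satisfies the verbal contract: 0 concentrated, 1 even", {
  conc <- matrix(0, 10, 10); conc[1, 2] <- conc[2, 1] <- 10
  expect_equal(network_diversity(tie_matrix(conc, paste0("p", 1:10)))$div, 0)

  even <- matrix(1, 10, 10); diag(even) <- 0
  expect_equal(network_diversity(tie_matrix(even, paste0("p", 1:10)))$div, 1)

  # 10 exchanges spread one-each over 10 of the 45 pairs
  w <- matrix(0, 10, 10)
  pairs <- which(upper.tri(w), arr.ind = TRUE)[1:10, ]
  w[pairs] <- 1; w <- w + t(w)
  d <- network_diversity(tie_matrix(w, paste0("p", 1:10)))
  expect_equal(d$div, log(10) / log(45), tolerance = 1e-12)
  expect_equal(d$entropy, log(10), tolerance = 1e-12)
  expect_equal(d$max_entropy, log(45), tolerance = 1e-12)

  # PT = 1: normalization log(1) = 0 is undefined
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(network_diversity(tie_matrix(two, c("a", "b"))), "undefined")
  expect_error(network_diversity(tie_matrix(matrix(0, 5, 5), letters[1:5])),
               "no interactions")
})

test_that("diversity is invariant to relabeling, scaling, and log base", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    m <- random_tie_matrix(n)
    d <- network_diversity(m)
    expect_gte(d$div, 0); expect_lte(d$div, 1)
    perm <- sample(n)
    expect_equal(network_diversity(tie_matrix(m$weights[perm, perm],
                                              m$actors[perm]))$div,
                 d$div, tolerance = 1e-12)
    k <- sample(2:7, 1)
    expect_equal(network_diversity(tie_matrix(m$weights * k, m$actors))$div,
                 d$div, tolerance = 1e-12)
    # base cancels in H / log(PT)
    p <- pair_distribution(m)
    expect_equal(shannon_entropy(p, base = 2) / log2(d$possible_ties),
                 d$div, tolerance = 1e-12)
  }
})

test_that("evening transfers never decrease entropy (Pigou-Dalton)", {
  set.seed(2024)
  for (rep in 1:1000) {
    n <- sample(4:8, 1)
    m <- random_tie_matrix(n, n_pos = sample(2:5, 1))
    h0 <- shannon_entropy(pair_distribution(m))
    # move one exchange from a heavier pair to a strictly lighter pair
    w <- m$weights
    up <- which(upper.tri(w), arr.ind = TRUE)
    wt <- w[up]
    heavy <- which(wt == max(wt))[1]
    light <- which(wt < wt[heavy])
    if (!length(light)) next
    light <- light[sample(length(light), 1)]
    wt[heavy] <- wt[heavy] - 1; wt[light] <- wt[light] + 1
    w2 <- matrix(0, n, n); w2[up] <- wt; w2 <- w2 + t(w2)
    h1 <- shannon_entropy(pair_distribution(tie_matrix(w2, m$actors)))
    expect_gte(h1, h0 - 1e-12)
  }
})

test_that("role-pair aggregation groups exchanges by unordered role pair", {
  ros <- actor_roster(c("stategov1", "insurer1", "patient1", "physician1"),
                      c("state_government", "insurance_company",
                        "patient", "physician"))
  log <- make_log(c("stategov1", "patient1"), c("insurer1", "physician1"),
                  count = c(3, 2), scenario = c("s1", "s2"))
  rp <- role_pair_counts(log, ros)
  expect_equal(rp$counts["state_government", "insurance_company"], 3)
  expect_equal(rp$counts["insurance_company", "state_government"], 3)
  expect_equal(rp$counts["patient", "physician"], 2)
  expect_true(isSymmetric(rp$counts))
  # grand total over distinct role pairs conserves the log total
  expect_equal(sum(rp$counts[upper.tri(rp$counts, diag = TRUE)]),
               sum(log$count))

  rp1 <- role_pair_counts(log, ros, scenario = "s1")
  expect_equal(sum(rp1$counts), 2 * 3)  # one off-diagonal cell, mirrored
  expect_equal(rp1$counts["patient", "physician"], 0)
  expect_error(role_pair_counts(log, ros, scenario = "nope"),
               "unknown scenario.*s1")

  empty <- role_pair_counts(make_log(character(), character(),
                                     count = integer(), time = integer(),
                                     scenario = character()), ros)
  expect_true(all(empty$counts == 0))
})

test_that("within-role exchanges land on the diagonal and conserve totals", {
  ros <- actor_roster(c("pat1", "pat2", "doc1"),
                      c("patient", "patient", "physician"))
  log <- make_log(c("pat1", "pat2"), c("pat2", "doc1"), count = c(5, 1))
  rp <- role_pair_counts(log, ros)
  expect_equal(rp$counts["patient", "patient"], 5)
  expect_equal(rp$counts["patient", "physician"], 1)
  expect_equal(sum(rp$counts[upper.tri(rp$counts, diag = TRUE)]),
               sum(log$count))
})
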