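test_that("identical config and seed reproduce the run bit-for-bit", {
  cfg <- aca_game_config(seed = 123)
  r1 <- simulate_game(cfg)
  r2 <- simulate_game(cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$events, r2$events)
  # and a different seed changes the log
  r3 <- simulate_game(aca_game_config(seed = 124))
  expect_false(identical(r1$log, r3$log))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(simulate_game(aca_game_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("engagement scores equal log participation counts exactly", {
  run <- simulate_game(aca_game_config(seed = 9))
  log <- run$log
  for (sc in unique(run$scores$scenario)) {
    sub <- log[log$scenario == sc, ]
    for (p in run$roster$actor_id) {
      expected <- sum(sub$count[sub$sender == p]) +
        sum(sub$count[sub$receiver == p])
      got <- run$scores$engagement_score[run$scores$player == p &
                                         run$scores$scenario == sc]
      expect_equal(got, expected)
    }
  }
  # totals reproducible from components
  expect_equal(run$scores$total,
               run$scores$task_score +
                 run$config$engagement_weight * run$scores$engagement_score)
})

test_that("every emitted record satisfies the log invariants", {
  run <- simulate_game(aca_game_config(seed = 31))
  expect_true(all(run$log$sender != run$log$receiver))
  expect_true(all(run$log$count >= 1))
  scen_labels <- vapply(run$config$scenarios, `[[`, character(1), "label")
  expect_true(all(run$log$scenario %in% scen_labels))
  for (sc in scen_labels)
    expect_false(is.unsorted(run$log$time[run$log$scenario == sc]))
  expect_true(all(c(run$log$sender, run$log$receiver) %in%
                  run$roster$actor_id))
  # one environmental event per role per round
  expect_equal(nrow(run$events),
               6 * sum(vapply(run$config$scenarios, `[[`, integer(1),
                              "rounds")))
})

test_that("a near-zero exchange rate yields a silent game with zero engagement", {
  cfg <- aca_game_config(seed = 2, exchanges_per_round = 1e-9, rounds = 3)
  run <- simulate_game(cfg)
  expect_equal(nrow(run$log), 0)
  expect_true(all(run$scores$engagement_score == 0))
})

test_that("pair propensities respect seeding, masking and the concentration limit", {
  cfg <- aca_game_config(seed = 5)
  ros <- config_roster(cfg)
  set.seed(1); v1 <- sample_pair_propensities(cfg, ros)
  set.seed(1); v2 <- sample_pair_propensities(cfg, ros)
  expect_identical(v1, v2)
  expect_equal(sum(v1), 1, tolerance = 1e-12)

  # masking: zero affinity silences patient <-> federal_government pairs
  aff <- cfg$affinity
  aff["patient", "federal_government"] <- 0
  aff["federal_government", "patient"] <- 0
  set.seed(2)
  v <- sample_pair_propensities(cfg, ros, affinity = aff)
  masked <- grepl("federal_government", names(v)) & grepl("patient", names(v))
  expect_true(any(masked))
  expect_true(all(v[masked] == 0))
  expect_true(all(v[!masked] > 0))

  # huge alpha: near-uniform propensities
  cfg_big <- aca_game_config(seed = 5, concentration = 1e6)
  set.seed(3)
  vb <- sample_pair_propensities(cfg_big, ros)
  expect_lt(max(vb) / min(vb), 1.05)

  # all-zero affinity is a configuration error
  expect_error(sample_pair_propensities(cfg, ros, affinity = aff * 0),
               "degenerate")
})

test_that("environmental events follow the configured categorical model", {
  cfg <- aca_game_config(seed = 1)
  cfg$event_model$patient <- list(outcomes = "A", probs = 1, utilities = 3)
  set.seed(10)
  draws <- replicate(20, sample_environment(cfg, "patient")$outcome)
  expect_true(all(draws == "A"))

  cfg$event_model$hospital <- list(outcomes = c("A", "B"),
                                   probs = c(0.3, 0.7),
                                   utilities = c(1, -1))
  set.seed(11)
  out <- replicate(10000, sample_environment(cfg, "hospital")$outcome)
  phat <- mean(out == "A")
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(phat - 0.3), 3 * se)

  expect_error(sample_environment(cfg, "alien"), "no event model")
})

test_that("config validation enumerates all violations in one error", {
  cfg <- aca_game_config(seed = 1)
  bad <- cfg
  bad$concentration <- -1
  bad$exchanges_per_round <- 0
  bad$scenarios[[1]]$rounds <- 0
  err <- tryCatch(validate_game_config(bad), error = function(e)
    conditionMessage(e))
  expect_match(err, "alpha")
  expect_match(err, "lambda")
  expect_match(err, "rounds")
})

test_that("the roster generated from a config is well-formed", {
  cfg <- aca_game_config(players_per_role = 3, seed = 1)
  ros <- config_roster(cfg)
  expect_equal(nrow(ros), 18)
  expect_equal(sum(ros$is_focal), 1)
  expect_equal(unname(table(ros$role)[default_roles()]),
               rep(3L, 6), ignore_attr = TRUE)
})
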