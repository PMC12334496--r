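test_that("the Bellman update reduces to its closed forms", {
  g <- cached_graph(2, 5)
  s <- c(0L, 0L); a <- c(1L, 0L); ns <- s + a
  pid <- getFromNamespace("pair_id", "paddleRL")
  # alpha = 1, gamma = 0: the entry becomes the reward
  q <- numeric(g$n_pairs)
  q1 <- bellman_update(q, g, s, a, reward = 0.05, ns, alpha = 1, gamma = 0)
  expect_equal(q1[pid(g, s, a)], 0.05)
  expect_equal(sum(q1 != 0), 1L)
  # generic arithmetic with a known successor maximum
  q <- numeric(g$n_pairs)
  ni <- which(colSums(t(g$states) != ns) == 0L)
  q[(g$state_off[ni] + 1L):g$state_off[ni + 1L]] <- 2
  q2 <- bellman_update(q, g, s, a, reward = 1, ns, alpha = 0.5, gamma = 0.99)
  expect_equal(q2[pid(g, s, a)], 0.5 * (1 + 0.99 * 2))
  # alpha = 0 leaves the table untouched
  q3 <- bellman_update(q, g, s, a, reward = 123, ns, alpha = 0, gamma = 0.5)
  expect_identical(q3, q)
  expect_error(bellman_update(q, g, s, c(0L, 0L), 0, s, 1, 0), "unavailable")
})

test_that("epsilon-greedy selection masks unavailable actions and is uniform when exploring", {
  g <- cached_graph(2, 5)
  # distinct Q values, epsilon = 0: the maximizer, deterministically
  set.seed(1)
  q <- seq_len(g$n_pairs) / g$n_pairs
  s <- c(1L, -2L)
  si <- which(colSums(t(g$states) != s) == 0L)
  ids <- (g$state_off[si] + 1L):g$state_off[si + 1L]
  best <- g$actions[g$edge_action[ids[which.max(q[ids])]], ]
  for (rep in 1:10) expect_identical(select_action(q, g, s, 0), best)
  # at the corner state only inward moves exist; never an unavailable action
  corner <- c(5L, 5L)
  for (rep in 1:50) {
    a <- select_action(q, g, corner, 1)
    expect_true(all(a <= 0L))
    expect_true(any(a != 0L))
  }
  # epsilon = 1 draws uniformly over the available actions
  set.seed(42)
  draws <- t(replicate(4000, select_action(q, g, s, 1)))
  counts <- table(paste(draws[, 1], draws[, 2]))
  expect_length(counts, 8L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("training solves a toy chain to its oracle optimum", {
  # two nested loops sharing state 1: the outer 3-cycle pays better on
  # average than the inner 2-cycle
  g <- toy_graph(from = c(1, 1, 2, 3, 4), to = c(2, 4, 3, 1, 1),
                 reward = c(0, 1, 2, 4, -1))
  opt <- max_mean_cycle(g)
  expect_equal(opt$mean_reward, 2)
  fit <- q_train(g, train_config(gamma = 0.9, episodes = 30,
                                 steps_per_episode = 2000, seed = 1))
  # greedy policy follows the oracle cycle at every state on it
  for (k in seq_len(nrow(opt$cycle))) {
    si <- opt$cycle$state[k]
    ids <- (g$state_off[si] + 1L):g$state_off[si + 1L]
    expect_equal(g$edge_next[ids[which.max(fit$q[ids])]],
                 opt$cycle$next_state[k])
  }
  expect_equal(tail(fit$history$greedy_speed, 1), 2)
})

test_that("training is bit-reproducible under a fixed seed", {
  g <- cached_graph(2, 5)
  cfg <- train_config(episodes = 3, steps_per_episode = 2000, seed = 7)
  f1 <- q_train(g, cfg)
  f2 <- q_train(g, cfg)
  expect_identical(f1$q, f2$q)
  expect_identical(f1$history, f2$history)
  f3 <- q_train(g, train_config(episodes = 3, steps_per_episode = 2000,
                                seed = 8))
  expect_false(identical(f1$q, f3$q))
})

test_that("schedules decay geometrically only in geometric mode", {
  g <- cached_graph(2, 5)
  fit <- q_train(g, train_config(episodes = 4, steps_per_episode = 100),
                 q_schedule(alpha_decay = 0.9, epsilon_decay = 0.8))
  expect_equal(fit$history$alpha, 0.9^(0:3))
  expect_equal(fit$history$epsilon, 0.8^(0:3))
  fix <- q_train(g, train_config(episodes = 4, steps_per_episode = 100),
                 q_schedule(epsilon0 = 0.3, epsilon_mode = "fixed"))
  expect_equal(fix$history$epsilon, rep(0.3, 4))
})

test_that("greedy rollout returns the periodic suffix and drops the transient", {
  g <- cached_graph(2, 5)
  # craft a Q table whose greedy policy funnels every state toward the
  # 2-cycle (0,0) <-> (1,1)
  q <- numeric(g$n_pairs)
  for (si in seq_len(g$n_states)) {
    s <- g$states[si, ]
    ids <- (g$state_off[si] + 1L):g$state_off[si + 1L]
    tgt <- pmax(pmin(-s, 1L), -1L)            # step toward (0, 0)
    if (all(s == c(0L, 0L))) tgt <- c(1L, 1L)
    if (all(s == c(1L, 1L))) tgt <- c(-1L, -1L)
    hit <- which(colSums(t(g$actions[g$edge_action[ids], , drop = FALSE])
                         != tgt) == 0L)
    q[ids[hit]] <- 1
  }
  cyc <- greedy_rollout(q, g, start_state = c(4L, -3L))
  expect_equal(cyc$N, 2L)
  expect_setequal(apply(cyc$states, 1, paste, collapse = ","),
                  c("0,0", "1,1"))
  # the 2-cycle is reciprocal: zero net displacement (scallop theorem)
  expect_lt(abs(stroke_speed(cyc)), 1e-9)
  # cycle mean reward is the definition of swimming speed
  expect_equal(stroke_speed(cyc), sum(cyc$rewards) / cyc$N)
})

test_that("rollouts from a dead end are an error", {
  g <- toy_graph(from = c(1, 2), to = c(2, 3), reward = c(1, 1))
  expect_error(greedy_rollout(numeric(2), g, start_state = 3L), "dead-end")
})

test_that("a trained two-paddle policy converges from every start to one limit cycle", {
  g <- cached_graph(2, 4)
  fit <- cached_training(2, 4)$fit
  opt <- max_mean_cycle(g)$mean_reward
  set.seed(42)
  starts <- sample(g$n_states, 15)
  speeds <- vapply(starts, function(si) {
    stroke_speed(greedy_rollout(fit, g, g$states[si, ]))
  }, numeric(1))
  expect_true(all(abs(speeds - opt) <= 0.02 * abs(opt)))
})

test_that("discounting too aggressively yields ineffective propulsion", {
  g <- cached_graph(2, 2)
  eff <- cached_training(2, 2, gamma = 0.99)$cycle
  expect_gte(stroke_speed(eff), 0.01)
  ineff <- cached_training(2, 2, gamma = 0.97)$cycle
  expect_lt(stroke_speed(ineff), 0.01)
})
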