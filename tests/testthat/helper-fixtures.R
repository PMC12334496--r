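# Shared fixtures: reward graphs and trainings are expensive (each reward is
# a set of Stokes solves), so they are built once per session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

default_params <- function() stokes_params()

cached_graph <- function(n, d) {
  key <- sprintf("graph-n%d-d%g", n, d)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_reward_graph(swimmer_geometry(n, d),
                                                default_params())
  }
  .fixture_cache[[key]]
}

# paper-protocol training (gamma/episodes/steps chosen by n_pairs)
cached_training <- function(n, d, seed = 1L, episodes = NULL, steps = NULL,
                            gamma = NULL) {
  if (is.null(gamma)) gamma <- if (n <= 2) 0.99 else 0.999
  if (is.null(episodes)) episodes <- 50L
  if (is.null(steps)) steps <- 50000L
  key <- sprintf("train-n%d-d%g-s%d-%d-%d-%g", n, d, seed, episodes, steps,
                 gamma)
  if (is.null(.fixture_cache[[key]])) {
    graph <- cached_graph(n, d)
    fit <- q_train(graph, train_config(gamma, episodes, steps, seed))
    .fixture_cache[[key]] <- list(fit = fit,
                                  cycle = greedy_rollout(fit, graph))
  }
  .fixture_cache[[key]]
}

# toy deterministic MDP from explicit edge lists (states are opaque ids;
# actions are per-state slots in the given order)
toy_graph <- function(from, to, reward) {
  S <- max(from, to)
  A <- max(tabulate(from))
  slot <- stats::ave(seq_along(from), from, FUN = seq_along)
  as_reward_graph <- getFromNamespace("as_reward_graph", "paddleRL")
  as_reward_graph(states = matrix(seq_len(S), ncol = 1),
                  actions = matrix(seq_len(A), ncol = 1),
                  edge_state = as.integer(from), edge_action = as.integer(slot),
                  edge_next = as.integer(to), edge_reward = reward)
}

# brute-force maximum mean cycle by DFS enumeration of simple cycles
brute_max_mean_cycle <- function(from, to, reward) {
  best <- -Inf
  n <- max(from, to)
  out <- split(seq_along(from), factor(from, levels = seq_len(n)))
  recurse <- function(path_v, path_e) {
    v <- path_v[length(path_v)]
    for (e in out[[v]]) {
      w <- to[e]
      if (w == path_v[1L]) {
        best <<- max(best, mean(reward[c(path_e, e)]))
      } else if (!(w %in% path_v)) {
        recurse(c(path_v, w), c(path_e, e))
      }
    }
  }
  for (v0 in seq_len(n)) recurse(v0, integer(0))
  best
}

# a rigid body-only cloud (no paddles), for drag comparisons
bare_body_cloud <- function(geom) {
  body <- geom$body
  mirror <- function(m) cbind(m[, 1], -m[, 2])
  pos <- rbind(body$top, body$axis, mirror(body$top))
  structure(list(pos = pos, vel = matrix(0, nrow(pos), 2),
                 label = rep("body", nrow(pos)),
                 n_top = nrow(body$top), n_axis = nrow(body$axis),
                 anchors_x = body$anchors_x, geom = geom),
            class = "point_cloud")
}
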