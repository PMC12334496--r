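#' Learning-rate and exploration schedules
#'
#' The learning rate `alpha` and exploration rate `epsilon` both start at 1
#' and decay geometrically by a factor 0.99 after each episode by default;
#' either can instead be held fixed (`mode = "fixed"`), which is the
#' baseline the decaying schedules are compared against.
#'
#' @param alpha0,epsilon0 initial rates in `[0, 1]`.
#' @param alpha_decay,epsilon_decay per-episode geometric factors in
#'   `(0, 1]`.
#' @param alpha_mode,epsilon_mode `"geometric"` or `"fixed"`.
#' @return an object of class `q_schedule`.
#' @export
q_schedule <- function(alpha0 = 1, epsilon0 = 1,
                       alpha_decay = 0.99, epsilon_decay = 0.99,
                       alpha_mode = c("geometric", "fixed"),
                       epsilon_mode = c("geometric", "fixed")) {
  stopifnot(alpha0 >= 0, alpha0 <= 1, epsilon0 >= 0, epsilon0 <= 1,
            alpha_decay > 0, alpha_decay <= 1,
            epsilon_decay > 0, epsilon_decay <= 1)
  structure(list(alpha0 = alpha0, epsilon0 = epsilon0,
                 alpha_decay = alpha_decay, epsilon_decay = epsilon_decay,
                 alpha_mode = match.arg(alpha_mode),
                 epsilon_mode = match.arg(epsilon_mode)),
            class = "q_schedule")
}

#' Training-loop configuration
#'
#' Defaults follow the two-paddle protocol: discount 0.99, 50 episodes of
#' 50,000 learning steps.  The three- and four-paddle protocols use
#' `gamma = 0.999` with 500 episodes of 500,000 steps.  The state is
#' re-randomized uniformly over the valid states at each episode start.
#'
#' @param gamma discount factor in `[0, 1)`.
#' @param episodes,steps_per_episode training-loop sizes.
#' @param seed integer RNG seed for Q initialization, exploration, and
#'   episode resets.
#' @param reset_each_episode re-randomize the state at episode starts.
#' @return an object of class `train_config`.
#' @export
train_config <- function(gamma = 0.99, episodes = 50L,
                         steps_per_episode = 50000L, seed = 1L,
                         reset_each_episode = TRUE) {
  stopifnot(gamma >= 0, gamma < 1, episodes >= 1, steps_per_episode >= 1)
  structure(list(gamma = gamma, episodes = as.integer(episodes),
                 steps_per_episode = as.integer(steps_per_episode),
                 seed = as.integer(seed),
                 reset_each_episode = isTRUE(reset_each_episode)),
            class = "train_config")
}

pair_id <- function(graph, state, action) {
  si <- match_row(graph$states, state)
  ai <- match_row(graph$actions, action)
  if (is.na(si) || is.na(ai)) return(0L)
  graph$pair_index[si, ai]
}

match_row <- function(m, x) {
  hit <- which(colSums(t(m) != x) == 0L)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' One Bellman update
#'
#' Replaces the entry for the available pair `(state, action)` by
#' `(1 - alpha) Q + alpha (r + gamma * max_a' Q(next_state, a'))`, the max
#' running over the actions available at the successor (0 if none); no other
#' entry is touched.
#'
#' @param q numeric Q vector aligned with the graph's pairs.
#' @param graph a [build_reward_graph()] result.
#' @param state,action the updated pair (must be available).
#' @param reward observed reward.
#' @param next_state successor state.
#' @param alpha learning rate.
#' @param gamma discount factor.
#' @return the updated Q vector.
#' @export
bellman_update <- function(q, graph, state, action, reward, next_state,
                           alpha, gamma) {
  e <- pair_id(graph, state, action)
  if (e == 0L) stop("unavailable state-action pair")
  ni <- match_row(graph$states, next_state)
  lo <- graph$state_off[ni] + 1L
  hi <- graph$state_off[ni + 1L]
  maxn <- if (hi >= lo) max(q[lo:hi]) else 0
  q[e] <- (1 - alpha) * q[e] + alpha * (reward + gamma * maxn)
  q
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform draw over the actions available at
#' `state`, otherwise the available action maximizing Q; ties break to the
#' fixed lexicographic action order.  Unavailable actions are never
#' returned.
#'
#' @inheritParams bellman_update
#' @param epsilon exploration rate.
#' @return integer action tuple.
#' @export
select_action <- function(q, graph, state, epsilon) {
  si <- match_row(graph$states, state)
  lo <- graph$state_off[si] + 1L
  hi <- graph$state_off[si + 1L]
  if (hi < lo) stop("dead-end state: no available action")
  ids <- lo:hi
  e <- if (stats::runif(1) < epsilon) {
    ids[sample.int(length(ids), 1L)]
  } else {
    ids[which.max(q[ids])]
  }
  graph$actions[graph$edge_action[e], ]
}

#' Train a tabular Q-learning paddler
#'
#' Runs `episodes x steps_per_episode` Bellman updates on the cached reward
#' graph with epsilon-greedy exploration.  Q is initialized with small
#' uniform noise on `[0, 1e-3]` from the run seed (small enough that
#' optimistic-initialization artifacts do not dominate); `alpha` and
#' `epsilon` follow the schedule, decaying after each episode; the state is
#' re-randomized uniformly over valid states at each episode start.  After
#' each episode the greedy limit-cycle speed from the rest configuration is
#' recorded, giving the learning curve.
#'
#' @param graph a [build_reward_graph()] result.
#' @param config a [train_config()].
#' @param schedule a [q_schedule()].
#' @return list of class `q_training`: `q` (values over available pairs),
#'   `history` (one row per episode: the schedule values, the greedy
#'   limit-cycle speed, and `behavior_speed`, the mean displacement per step
#'   actually achieved while training -- the speed an observer would see,
#'   exploration noise included), and the echoed configuration.
#' @export
q_train <- function(graph, config = train_config(),
                    schedule = q_schedule()) {
  set.seed(config$seed)
  q0 <- stats::runif(graph$n_pairs, 0, 1e-3)
  resets <- which(diff(graph$state_off) > 0L)
  start <- rollout_start_state(graph)
  res <- train_cpp(graph$edge_next - 1L, graph$edge_reward,
                   graph$state_off, q0,
                   resets - 1L, start - 1L,
                   config$episodes, config$steps_per_episode, config$gamma,
                   schedule$alpha0, schedule$epsilon0,
                   schedule$alpha_decay, schedule$epsilon_decay,
                   schedule$alpha_mode == "geometric",
                   schedule$epsilon_mode == "geometric",
                   config$reset_each_episode)
  structure(list(q = res$q,
                 history = data.frame(episode = seq_len(config$episodes),
                                      alpha = res$alpha,
                                      epsilon = res$epsilon,
                                      greedy_speed = res$greedy_speed,
                                      behavior_speed = res$behavior_speed),
                 config = config, schedule = schedule),
            class = "q_training")
}

#' @export
print.q_training <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(
    "<q_training> %d episodes x %d steps, gamma %g; final greedy speed %.4g\n",
    x$config$episodes, x$config$steps_per_episode, x$config$gamma,
    x$history$greedy_speed[n]))
  invisible(x)
}

# canonical rollout start: the rest configuration if valid, else the first
# state with an available action
rollout_start_state <- function(graph) {
  zero <- match_row(graph$states, rep(0L, ncol(graph$states)))
  if (!is.na(zero) && graph$state_off[zero + 1L] > graph$state_off[zero]) {
    return(zero)
  }
  which(diff(graph$state_off) > 0L)[1L]
}

#' Greedy rollout and limit-cycle extraction
#'
#' Follows the greedy (`epsilon = 0`) policy from `start_state`.  The policy
#' and transitions are deterministic over a finite state set, so a state
#' must recur within `n_states + 1` steps; the periodic suffix is returned
#' as the stroke cycle and the transient is discarded.
#'
#' @param q a [q_train()] result or a bare numeric Q vector.
#' @param graph a [build_reward_graph()] result.
#' @param start_state integer state tuple (default: the rest configuration).
#' @return a [stroke_cycle()] object.
#' @export
greedy_rollout <- function(q, graph, start_state = NULL) {
  if (inherits(q, "q_training")) q <- q$q
  si <- if (is.null(start_state)) {
    rollout_start_state(graph)
  } else {
    match_row(graph$states, start_state)
  }
  if (is.na(si)) stop("start state is not a valid state of the graph")
  S <- graph$n_states
  visit <- integer(S)
  path <- integer(S + 1L)
  t <- 0L
  repeat {
    if (visit[si] > 0L) {
      ids <- path[visit[si]:t]
      return(stroke_cycle(
        states = graph$states[graph$edge_state[ids], , drop = FALSE],
        actions = graph$actions[graph$edge_action[ids], , drop = FALSE],
        rewards = graph$edge_reward[ids]))
    }
    lo <- graph$state_off[si] + 1L
    hi <- graph$state_off[si + 1L]
    if (hi < lo) stop("greedy rollout reached a dead-end state")
    e <- (lo:hi)[which.max(q[lo:hi])]
    t <- t + 1L
    visit[si] <- t
    path[t] <- e
    si <- graph$edge_next[e]
  }
}
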