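#' Enumerate the action space
#'
#' All `3^n - 1` n-tuples over `{-1, 0, 1}` excluding the all-zero tuple
#' (at least one paddle must move at every step), in lexicographic order
#' (first coordinate most significant).  This fixed order is the tie-break
#' order used everywhere downstream.
#'
#' @param n number of paddle pairs.
#' @return integer matrix, one action per row.
#' @export
enumerate_actions <- function(n) {
  stopifnot(n >= 1)
  vals <- rep(list(c(-1L, 0L, 1L)), n)
  g <- as.matrix(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_len(n)), drop = FALSE]     # col 1 = a_1, most significant
  dimnames(g) <- NULL
  g[rowSums(g != 0L) > 0L, , drop = FALSE]
}

#' Enumerate the valid states of a geometry
#'
#' All n-tuples over `[-state_bound, state_bound]` whose configuration is
#' collision-free (see [is_valid_state()]), in lexicographic order.
#'
#' @param geom a [swimmer_geometry()].
#' @return integer matrix, one state per row.
#' @export
enumerate_states <- function(geom) {
  b <- geom$state_bound
  n <- geom$n_pairs
  vals <- rep(list(seq.int(-b, b)), n)
  g <- as.matrix(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_len(n)), drop = FALSE]
  dimnames(g) <- NULL
  ok <- vapply(seq_len(nrow(g)), function(i) is_valid_state(geom, g[i, ]),
               logical(1))
  g[ok, , drop = FALSE]
}

state_key <- function(s, bound = 5L) {
  base <- 2L * bound + 1L
  sum((s + bound) * base^(seq_along(s) - 1L)) + 1L
}

graph_config <- function(geom, params) {
  list(format = "paddleRL-reward-graph-1",
       n_pairs = geom$n_pairs, spacing = geom$spacing,
       body_length = geom$body_length, cap_radius = geom$cap_radius,
       paddle_length = geom$paddle_length,
       point_spacing = geom$point_spacing,
       theta_step = geom$theta_step, state_bound = geom$state_bound,
       relaxed_layout = geom$relaxed_layout,
       mu = params$mu, epsilon = params$epsilon,
       quadrature_nodes = params$quadrature_nodes)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Build (or load) the deterministic reward graph
#'
#' Enumerates every available state-action pair of the paddling MDP and
#' solves the fluid problem for its displacement reward, so that training
#' afterwards runs at table-lookup speed.  The environment is deterministic
#' (`next_state = state + action`), rewards obey the reflection antisymmetry
#' `r(s, a) = -r(mirror(s), mirror(a))`, and the builder exploits that
#' antisymmetry: only one member of each mirror pair is solved and
#' self-mirrored moves carry an exactly zero reward.
#'
#' With a `cache_dir`, the edge table is persisted as CSV next to a JSON
#' sidecar (config echo, content hash, counts); a rebuild with an identical
#' configuration is a cache hit and reproduces the graph bit-identically.
#'
#' @param geom a [swimmer_geometry()].
#' @param params a [stokes_params()].
#' @param cache_dir optional directory for the on-disk cache.
#' @param progress emit progress messages.
#' @return an object of class `reward_graph` with the state/action tables,
#'   the edge arrays (CSR-indexed by state), and counts.
#' @export
build_reward_graph <- function(geom, params = stokes_params(),
                               cache_dir = NULL, progress = FALSE) {
  config <- graph_config(geom, params)
  hash <- config_hash(config)
  cache_csv <- if (!is.null(cache_dir)) {
    file.path(cache_dir, paste0("graph-", hash, ".csv"))
  }

  states <- enumerate_states(geom)
  actions <- enumerate_actions(geom$n_pairs)
  S <- nrow(states); A <- nrow(actions)
  bound <- geom$state_bound
  base <- 2L * bound + 1L
  lookup <- integer(base^geom$n_pairs)
  for (i in seq_len(S)) lookup[state_key(states[i, ], bound)] <- i

  # availability: bounds + valid successor + collision-free interior times
  ts <- gauss01(3L)$nodes
  edge_state <- integer(0); edge_action <- integer(0); edge_next <- integer(0)
  es <- ea <- en <- vector("list", S)
  for (i in seq_len(S)) {
    s <- states[i, ]
    keep <- integer(0); nxt <- integer(0)
    for (ai in seq_len(A)) {
      a <- actions[ai, ]
      ns <- s + a
      if (any(abs(ns) > bound)) next
      j <- lookup[state_key(ns, bound)]
      if (j == 0L) next
      bad <- FALSE
      if (geom$n_pairs > 1L) {
        for (t in ts) {
          if (config_collides(geom, (s + a * t) * geom$theta_step)) {
            bad <- TRUE; break
          }
        }
      }
      if (!bad) { keep <- c(keep, ai); nxt <- c(nxt, j) }
    }
    es[[i]] <- rep.int(i, length(keep)); ea[[i]] <- keep; en[[i]] <- nxt
  }
  edge_state <- unlist(es); edge_action <- unlist(ea); edge_next <- unlist(en)
  E <- length(edge_state)

  pair_index <- matrix(0L, S, A)
  pair_index[cbind(edge_state, edge_action)] <- seq_len(E)

  reward <- rep(NA_real_, E)
  if (!is.null(cache_csv) && file.exists(cache_csv)) {
    dt <- data.table::fread(cache_csv, colClasses = list(character = "reward"))
    if (nrow(dt) != E) stop("reward-graph cache is inconsistent: ", cache_csv)
    reward <- as.numeric(dt$reward)
  } else {
    mirror_perm <- rev(seq_len(geom$n_pairs))
    done <- 0L
    for (e in seq_len(E)) {
      if (!is.na(reward[e])) next
      s <- states[edge_state[e], ]
      a <- actions[edge_action[e], ]
      ms <- -s[mirror_perm]; ma <- -a[mirror_perm]
      mi <- lookup[state_key(ms, bound)]
      mai <- which(colSums(t(actions) != ma) == 0L)
      me <- pair_index[mi, mai]
      if (me == e) {
        reward[e] <- 0                       # self-mirrored: exact zero
      } else {
        r <- move_displacement_unchecked(geom, s, a, params)
        reward[e] <- r
        reward[me] <- -r
      }
      done <- done + 1L
      if (progress && done %% 500L == 0L) {
        message("  rewards: ", sum(!is.na(reward)), "/", E)
      }
    }
    if (!is.null(cache_csv)) {
      dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
      dt <- data.table::data.table(
        state = apply(states[edge_state, , drop = FALSE], 1, paste,
                      collapse = " "),
        action = apply(actions[edge_action, , drop = FALSE], 1, paste,
                       collapse = " "),
        next_state = apply(states[edge_next, , drop = FALSE], 1, paste,
                           collapse = " "),
        # 17 significant digits: doubles survive the CSV round trip exactly
        reward = sprintf("%.17g", reward))
      data.table::fwrite(dt, cache_csv)
      jsonlite::write_json(
        list(config = config, hash = hash, n_states = S, n_pairs = E,
             package = as.character(utils::packageVersion("paddleRL"))),
        sub("\\.csv$", ".json", cache_csv), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }
  }

  state_off <- c(0L, cumsum(tabulate(edge_state, nbins = S)))
  structure(list(states = states, actions = actions,
                 edge_state = edge_state, edge_action = edge_action,
                 edge_next = edge_next, edge_reward = reward,
                 state_off = state_off, pair_index = pair_index,
                 n_states = S, n_pairs = E,
                 geom = geom, params = params,
                 config = config, hash = hash),
            class = "reward_graph")
}

#' @export
print.reward_graph <- function(x, ...) {
  cat(sprintf(
    "<reward_graph> n = %d, d = %g: %d states, %d state-action pairs\n",
    x$geom$n_pairs, x$geom$spacing, x$n_states, x$n_pairs))
  invisible(x)
}

# assemble a reward_graph-shaped object from explicit tables (toy MDPs)
as_reward_graph <- function(states, actions, edge_state, edge_action,
                            edge_next, edge_reward) {
  o <- order(edge_state, edge_action)
  edge_state <- edge_state[o]; edge_action <- edge_action[o]
  edge_next <- edge_next[o]; edge_reward <- edge_reward[o]
  S <- nrow(states); A <- nrow(actions); E <- length(edge_state)
  pair_index <- matrix(0L, S, A)
  pair_index[cbind(edge_state, edge_action)] <- seq_len(E)
  structure(list(states = states, actions = actions,
                 edge_state = edge_state, edge_action = edge_action,
                 edge_next = edge_next, edge_reward = edge_reward,
                 state_off = c(0L, cumsum(tabulate(edge_state, nbins = S))),
                 pair_index = pair_index,
                 n_states = S, n_pairs = E,
                 geom = NULL, params = NULL, config = NULL, hash = NULL),
            class = "reward_graph")
}

#' Export the reward graph as a data frame
#'
#' @param graph a [build_reward_graph()] result.
#' @return data.frame with state, action, next-state tuples and rewards.
#' @export
reward_graph_table <- function(graph) {
  n <- ncol(graph$states)
  out <- data.frame(
    graph$states[graph$edge_state, , drop = FALSE],
    graph$actions[graph$edge_action, , drop = FALSE],
    graph$states[graph$edge_next, , drop = FALSE],
    reward = graph$edge_reward)
  names(out) <- c(paste0("s", seq_len(n)), paste0("a", seq_len(n)),
                  paste0("next_s", seq_len(n)), "reward")
  out
}

#' Exact optimal average-speed cycle (maximum mean-weight cycle)
#'
#' Computes, exactly, a cycle of the reward graph maximizing the mean edge
#' reward, i.e. the best achievable average displacement per move of any
#' periodic stroke.  Uses Karp's algorithm on each strongly connected
#' component, then extracts a realizing cycle from the critical subgraph of
#' tight edges.  The result upper-bounds the mean reward of every greedy
#' cycle a trained policy can produce.
#'
#' @param graph a [build_reward_graph()] result (or any object of that
#'   shape).
#' @return list with `mean_reward` and `cycle`, the latter a data frame of
#'   edge indices (`state`, `action`, `next`, `reward` as row indices into
#'   the graph's tables), plus `edge`, the edge ids.
#' @export
max_mean_cycle <- function(graph) {
  E <- graph$n_pairs
  if (E == 0L) stop("empty reward graph")
  g <- igraph::graph_from_edgelist(
    cbind(graph$edge_state, graph$edge_next), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")$membership
  best <- list(mean = -Inf, edges = NULL)
  for (cid in unique(comp)) {
    verts <- which(comp == cid)
    if (length(verts) < 2L) next       # no self-loops: need >= 2 states
    eid <- which(comp[graph$edge_state] == cid &
                   comp[graph$edge_next] == cid)
    if (length(eid) == 0L) next
    res <- karp_component(match(graph$edge_state[eid], verts),
                          match(graph$edge_next[eid], verts),
                          graph$edge_reward[eid], length(verts))
    if (res$mean > best$mean) {
      best <- list(mean = res$mean, edges = eid[res$cycle_edges])
    }
  }
  if (!is.finite(best$mean)) stop("reward graph has no cycle")
  e <- best$edges
  list(mean_reward = best$mean,
       cycle = data.frame(state = graph$edge_state[e],
                          action = graph$edge_action[e],
                          next_state = graph$edge_next[e],
                          reward = graph$edge_reward[e]),
       edge = e)
}

# Karp's maximum mean cycle on one strongly connected component
# (local vertex ids 1..V), plus critical-subgraph cycle extraction.
karp_component <- function(u, v, w, V) {
  E <- length(u)
  by_dst <- split(seq_len(E), v)
  d <- matrix(-Inf, V + 1L, V)     # d[k+1, x] = max weight of k-edge walk
  d[1L, 1L] <- 0
  for (k in seq_len(V)) {
    cand <- d[k, u] + w
    dk <- rep(-Inf, V)
    for (nm in names(by_dst)) {
      dk[as.integer(nm)] <- max(cand[by_dst[[nm]]])
    }
    d[k + 1L, ] <- dk
  }
  dV <- d[V + 1L, ]
  mu_best <- -Inf
  for (x in which(is.finite(dV))) {
    ks <- which(is.finite(d[seq_len(V), x]))      # k+1 indices
    m <- min((dV[x] - d[ks, x]) / (V - (ks - 1L)))
    if (m > mu_best) mu_best <- m
  }
  # critical subgraph of w' = w - mu*: longest-path potentials, tight edges
  wp <- w - mu_best
  h <- rep(0, V)
  for (it in seq_len(2L * V + 5L)) {
    cand <- h[u] + wp
    hn <- h
    for (nm in names(by_dst)) {
      x <- as.integer(nm)
      hn[x] <- max(hn[x], max(cand[by_dst[[nm]]]))
    }
    if (max(abs(hn - h)) < 1e-13 * max(1, max(abs(h)))) { h <- hn; break }
    h <- hn
  }
  scale <- max(1, max(abs(w)))
  for (tol in c(1e-9, 1e-7, 1e-5) * scale) {
    tight <- which(h[u] + wp - h[v] > -tol)
    cyc <- find_cycle_edges(u[tight], v[tight], V)
    if (!is.null(cyc)) {
      ce <- tight[cyc]
      m <- mean(w[ce])
      if (abs(m - mu_best) <= 1e-8 * scale) {
        return(list(mean = mu_best, cycle_edges = ce))
      }
    }
  }
  stop("max_mean_cycle: failed to extract a realizing cycle")
}

# any directed cycle in the given edge set, as edge positions (or NULL)
find_cycle_edges <- function(u, v, V) {
  out <- split(seq_along(u), factor(u, levels = seq_len(V)))
  color <- integer(V)                  # 0 white, 1 on stack, 2 done
  parent_edge <- integer(V)
  for (root in seq_len(V)) {
    if (color[root] != 0L || length(out[[root]]) == 0L) next
    stack <- list(list(x = root, i = 1L))
    color[root] <- 1L
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      es <- out[[top$x]]
      if (top$i > length(es)) {
        color[top$x] <- 2L
        stack[[length(stack)]] <- NULL
        next
      }
      stack[[length(stack)]]$i <- top$i + 1L
      e <- es[top$i]
      y <- v[e]
      if (color[y] == 1L) {            # back edge: walk the stack
        cyc <- e
        k <- length(stack)
        while (stack[[k]]$x != y) {
          cyc <- c(parent_edge[stack[[k]]$x], cyc)
          k <- k - 1L
        }
        return(cyc)
      }
      if (color[y] == 0L) {
        color[y] <- 1L
        parent_edge[y] <- e
        stack[[length(stack) + 1L]] <- list(x = y, i = 1L)
      }
    }
  }
  NULL
}
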