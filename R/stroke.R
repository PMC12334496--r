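#' A periodic stroke cycle
#'
#' An ordered list of moves `(state, action, reward)` of period `N` (one
#' time unit per move); applying the actions in order returns to the first
#' state.
#'
#' @param states integer `N x n` matrix, the state at the start of each
#'   move.
#' @param actions integer `N x n` matrix of moves.
#' @param rewards numeric displacement per move.
#' @return an object of class `stroke_cycle`.
#' @export
stroke_cycle <- function(states, actions, rewards) {
  states <- rbind(states); actions <- rbind(actions)
  N <- nrow(states)
  stopifnot(nrow(actions) == N, length(rewards) == N,
            ncol(states) == ncol(actions))
  nxt <- states + actions
  if (!all(nxt[-N, , drop = FALSE] == states[-1L, , drop = FALSE]) ||
      !all(nxt[N, ] == states[1L, ])) {
    stop("not a cycle: actions do not chain back to the first state")
  }
  structure(list(states = states, actions = actions,
                 rewards = as.numeric(rewards), N = N,
                 n_pairs = ncol(states)),
            class = "stroke_cycle")
}

#' @export
print.stroke_cycle <- function(x, ...) {
  cat(sprintf("<stroke_cycle> N = %d moves, %d paddle pair(s), U = %.4g\n",
              x$N, x$n_pairs, stroke_speed(x)))
  invisible(x)
}

#' Convert an oracle cycle to a stroke cycle
#'
#' @param graph the reward graph the cycle lives on.
#' @param edges edge ids in cycle order (e.g. `max_mean_cycle()$edge`).
#' @return a [stroke_cycle()].
#' @export
as_stroke_cycle <- function(graph, edges) {
  stroke_cycle(graph$states[graph$edge_state[edges], , drop = FALSE],
               graph$actions[graph$edge_action[edges], , drop = FALSE],
               graph$edge_reward[edges])
}

#' Swimming speed of a stroke
#'
#' Mean displacement per move, `U = (1/N) sum r(s_n, a_n)`.
#'
#' @param cycle a [stroke_cycle()].
#' @return scalar speed, length units per unit time.
#' @export
stroke_speed <- function(cycle) mean(cycle$rewards)

#' Power-stroke onset of a paddle
#'
#' The power stroke sweeps a paddle through a decreasing sequence of states
#' (an arc to the left, producing forward thrust).  Operationally the onset
#' `T_j` is the 0-based index of the first move of paddle `j`'s longest
#' maximal run of consecutive `-1` moves, runs taken cyclically; ties break
#' to the earliest run.
#'
#' @param cycle a [stroke_cycle()].
#' @param paddle paddle index `j` (1 = rearmost).
#' @return integer move index in `0..N-1`, or `NA` (flagged with a warning)
#'   if the paddle never performs a `-1` move.
#' @export
power_stroke_start <- function(cycle, paddle) {
  a <- cycle$actions[, paddle]
  N <- cycle$N
  if (!any(a == -1L)) {
    warning("paddle ", paddle, " has no power stroke (no -1 move)")
    return(NA_integer_)
  }
  if (all(a == -1L)) return(0L)
  starts <- which(a == -1L & a[c(N, seq_len(N - 1L))] != -1L)
  run_len <- vapply(starts, function(s) {
    len <- 0L
    while (a[(s - 1L + len) %% N + 1L] == -1L) len <- len + 1L
    len
  }, integer(1))
  starts[which.max(run_len)] - 1L
}

#' Phase lag between adjacent paddle pairs
#'
#' `delta_phi = (T_j - T_{j+1}) / N`, wrapped into `[-0.5, 0.5]`, where `j`
#' is the more rearward paddle; negative values mean the back paddle leads
#' the power-stroke sequence (a back-to-front, antiplectic wave).
#'
#' @param cycle a [stroke_cycle()].
#' @param pair index `j` of the rearward paddle of the pair `(j, j + 1)`.
#' @return dimensionless phase lag in `[-0.5, 0.5]` (`NA` if either onset is
#'   undefined).
#' @export
phase_lag <- function(cycle, pair) {
  stopifnot(pair >= 1, pair + 1 <= cycle$n_pairs)
  tb <- suppressWarnings(power_stroke_start(cycle, pair))
  tf <- suppressWarnings(power_stroke_start(cycle, pair + 1L))
  if (is.na(tb) || is.na(tf)) return(NA_real_)
  wrap_half((tb - tf) / cycle$N)
}

wrap_half <- function(x) x - round(x)

#' Amplitude of a paddle's motion
#'
#' Range of motion used during the stroke, `(max s - min s) * theta_step`;
#' always a multiple of the angular grid step.
#'
#' @param cycle a [stroke_cycle()].
#' @param paddle paddle index.
#' @param theta_step angular grid step, radians.
#' @return amplitude in radians.
#' @export
paddle_amplitude <- function(cycle, paddle, theta_step = pi / 20) {
  s <- cycle$states[, paddle]
  (max(s) - min(s)) * theta_step
}

#' Classify the coordination pattern of a stroke
#'
#' `back_to_front` (antiplectic wave) if every adjacent phase lag is
#' negative, `front_to_back` (symplectic) if every adjacent phase lag is
#' positive, `other` otherwise (mixed signs, undefined onsets, or a single
#' paddle).
#'
#' @param cycle a [stroke_cycle()].
#' @return one of `"back_to_front"`, `"front_to_back"`, `"other"`.
#' @export
classify_stroke <- function(cycle) {
  if (cycle$n_pairs < 2L) return("other")
  lags <- vapply(seq_len(cycle$n_pairs - 1L),
                 function(j) phase_lag(cycle, j), numeric(1))
  classify_from_lags(lags)
}

classify_from_lags <- function(lags) {
  if (any(is.na(lags)) || length(lags) == 0L) return("other")
  if (all(lags < 0)) return("back_to_front")
  if (all(lags > 0)) return("front_to_back")
  "other"
}

#' Lighthill efficiency of a stroke
#'
#' Computes the period-average power `P = (1/N) \int F(t) . U(t) dt` with
#' the same per-move Gauss quadrature as the rewards, the period-averaged
#' tow drag `zeta` over the `N` discrete configurations of the cycle
#' (paddles frozen per state), and the Lighthill efficiency
#' `eta = zeta U^2 / P` -- the power needed to tow the swimmer at its mean
#' speed relative to the power the stroke actually expends.
#'
#' The drag scale of a shape-changing swimmer is a convention; the
#' period-averaged frozen-configuration tow drag used here is recorded in
#' every metrics artifact, and efficiency comparisons should be read as
#' orderings under this convention.
#'
#' @param cycle a [stroke_cycle()].
#' @param geom the [swimmer_geometry()] the cycle was learned on.
#' @param params a [stokes_params()].
#' @return list with `zeta`, `power`, `eta`.
#' @export
stroke_efficiency <- function(cycle, geom, params = stokes_params()) {
  g <- gauss01(params$quadrature_nodes)
  Pbar <- 0
  zeta <- 0
  for (m in seq_len(cycle$N)) {
    s <- cycle$states[m, ]
    a <- cycle$actions[m, ]
    omega <- a * geom$theta_step
    for (k in seq_along(g$nodes)) {
      th <- (s + a * g$nodes[k]) * geom$theta_step
      cl <- discretize(geom, th, omega)
      sol <- solve_swim(cl, params)
      Pbar <- Pbar + g$weights[k] * instantaneous_power(sol, cl)
    }
    zeta <- zeta + tow_drag(discretize(geom, s * geom$theta_step), params)
  }
  Pbar <- Pbar / cycle$N
  zeta <- zeta / cycle$N
  U <- stroke_speed(cycle)
  eta <- if (Pbar > 0) zeta * U^2 / Pbar else 0
  list(zeta = zeta, power = Pbar, eta = eta)
}

#' Full stroke characterization
#'
#' Stroke length, swimming speed, adjacent phase lags, per-paddle
#' amplitudes, power, drag coefficient, Lighthill efficiency, and the
#' coordination label.
#'
#' @param cycle a [stroke_cycle()].
#' @param geom the [swimmer_geometry()] the cycle was learned on.
#' @param params a [stokes_params()].
#' @param efficiency set `FALSE` to skip the (more expensive) power and
#'   drag computations.
#' @return an object of class `stroke_metrics`.
#' @export
stroke_metrics <- function(cycle, geom, params = stokes_params(),
                           efficiency = TRUE) {
  n <- cycle$n_pairs
  lags <- if (n >= 2L) {
    vapply(seq_len(n - 1L), function(j) phase_lag(cycle, j), numeric(1))
  } else {
    numeric(0)
  }
  amps <- vapply(seq_len(n), function(j) {
    paddle_amplitude(cycle, j, geom$theta_step)
  }, numeric(1))
  eff <- if (efficiency) {
    stroke_efficiency(cycle, geom, params)
  } else {
    list(zeta = NA_real_, power = NA_real_, eta = NA_real_)
  }
  structure(list(n_pairs = n, N = cycle$N, U = stroke_speed(cycle),
                 phase_lags = lags, amplitudes = amps,
                 zeta = eff$zeta, power = eff$power, eta = eff$eta,
                 stroke_type = classify_from_lags(lags),
                 zeta_convention = "period-averaged frozen-state tow drag"),
            class = "stroke_metrics")
}

#' @export
print.stroke_metrics <- function(x, ...) {
  cat(sprintf("<stroke_metrics> %s stroke, N = %d, U = %.4g\n",
              x$stroke_type, x$N, x$U))
  if (length(x$phase_lags)) {
    cat("  phase lags:", paste(sprintf("%.3f", x$phase_lags),
                               collapse = ", "), "\n")
  }
  cat("  amplitudes (multiples of pi/20):",
      paste(sprintf("%.0f", x$amplitudes / (pi / 20)), collapse = ", "),
      "\n")
  if (!is.na(x$eta)) {
    cat(sprintf("  zeta = %.4g, P = %.4g, eta = %.4g\n",
                x$zeta, x$power, x$eta))
  }
  invisible(x)
}

#' Mirror a stroke cycle front-to-back
#'
#' Reverses the paddle order and negates states and actions; the mirrored
#' cycle swims at speed `-U` with identical amplitudes and `|phase lags|`.
#'
#' @param cycle a [stroke_cycle()].
#' @return the mirrored [stroke_cycle()].
#' @export
mirror_cycle <- function(cycle) {
  perm <- rev(seq_len(cycle$n_pairs))
  stroke_cycle(-cycle$states[, perm, drop = FALSE],
               -cycle$actions[, perm, drop = FALSE],
               -cycle$rewards)
}
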