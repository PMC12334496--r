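#' Fluid and quadrature parameters
#'
#' The fluid is Stokes flow with viscosity `mu` (the viscosity scales forces
#' and power but not the swimming velocity, since the kinematics are
#' prescribed).  `epsilon` is the regularization length of the 2D regularized
#' Stokeslet blob; the standard choice is half the discretization spacing.
#' Displacements over a unit move are integrated with `quadrature_nodes`
#' Gauss-Legendre nodes on (0, 1).
#'
#' @param mu dynamic viscosity.
#' @param epsilon regularization length, length units.
#' @param quadrature_nodes number of Gauss-Legendre nodes per move.
#' @return an object of class `stokes_params`.
#' @export
stokes_params <- function(mu = 1, epsilon = 0.05, quadrature_nodes = 3L) {
  stopifnot(mu > 0, epsilon > 0, quadrature_nodes >= 1)
  structure(list(mu = mu, epsilon = epsilon,
                 quadrature_nodes = as.integer(quadrature_nodes)),
            class = "stokes_params")
}

# Gauss-Legendre nodes/weights on [0, 1], cached per order
gauss01 <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      g <- pracma::gaussLegendre(n, 0, 1)
      cache[[key]] <- list(nodes = g$x, weights = g$w)
    }
    cache[[key]]
  }
})

#' Assemble the regularized-Stokeslet mobility matrix
#'
#' Builds the dense symmetric operator `M` mapping the stacked point forces
#' to stacked velocities, `U = M F`, from the two-dimensional regularized
#' Stokeslet with the radially symmetric blob of width `epsilon` (Cortez
#' regularization), scaled by `1/mu`.  With `R = sqrt(r^2 + epsilon^2)` the
#' kernel is
#' \deqn{S_\epsilon = \frac{1}{4\pi\mu}\Big[-\Big(\ln(R+\epsilon) -
#'   \frac{\epsilon(R+2\epsilon)}{(R+\epsilon)R}\Big) I +
#'   \frac{R+2\epsilon}{(R+\epsilon)^2 R}\, x \otimes x\Big],}
#' which is finite at zero separation and tends to the singular 2D Stokeslet
#' \eqn{(-I \ln r + x \otimes x / r^2)/(4\pi\mu)} in the far field.
#'
#' Rows/columns are interleaved `(x_1, y_1, x_2, y_2, ...)`.
#'
#' @param points a [discretize()] point cloud (or any list with a `pos`
#'   matrix of distinct coordinates).
#' @param params a [stokes_params()].
#' @return dense `2P x 2P` symmetric matrix.
#' @export
assemble_mobility <- function(points, params = stokes_params()) {
  pos <- points$pos
  stopifnot(is.matrix(pos), ncol(pos) == 2, nrow(pos) >= 1)
  assemble_mobility_cpp(pos, params$mu, params$epsilon)
}

#' Solve the force-free swimming problem
#'
#' Solves the bordered mobility system `M F - U0 = U_P`, `sum(F) = 0` for the
#' point forces and the rigid translational (swimming) velocity `U0`, given
#' the prescribed deformation velocities `U_P` of the point cloud.  By the
#' top/bottom symmetry of paddling the swimming velocity is horizontal; its
#' x-component is the instantaneous swimming speed `u0`.
#'
#' @param points a [discretize()] point cloud with deformation velocities.
#' @param params a [stokes_params()].
#' @return an object of class `swim_solve`: `forces` (P x 2),
#'   `swim_velocity` (length 2), `speed` (scalar `u0`).
#' @export
solve_swim <- function(points, params = stokes_params()) {
  sol <- tryCatch(
    solve_swim_cpp(points$pos, points$vel, params$mu, params$epsilon),
    error = function(e) {
      stop("mobility solve failed (singular or ill-conditioned system): ",
           conditionMessage(e))
    })
  structure(list(forces = sol$forces,
                 swim_velocity = as.numeric(sol$U0),
                 speed = sol$U0[1]),
            class = "swim_solve")
}

#' @export
print.swim_solve <- function(x, ...) {
  cat(sprintf("<swim_solve> u0 = %.6g, |sum F| = %.3g\n",
              x$speed, sqrt(sum(colSums(x$forces)^2))))
  invisible(x)
}

# fast path: solve only the mirror-symmetric half system and return u0
swim_speed_fast <- function(points, params) {
  nt <- points$n_top
  na <- points$n_axis
  idx_axis <- if (na > 0) nt + seq_len(na) else integer(0)
  solve_swim_sym_cpp(points$pos[seq_len(nt), , drop = FALSE],
                     points$vel[seq_len(nt), , drop = FALSE],
                     points$pos[idx_axis, , drop = FALSE],
                     points$vel[idx_axis, 1],
                     params$mu, params$epsilon)
}

#' Displacement reward of a move
#'
#' Net horizontal displacement of the swimmer over one unit-time move from
#' `state` under `action`: the configuration at time `t` is
#' `theta(0) + action * theta_step * t` with constant tilt rates
#' `action * theta_step`, and the instantaneous swimming speed is integrated
#' with Gauss-Legendre quadrature (3 nodes by default).  Positive rewards are
#' forward (+x) displacements.
#'
#' @param geom a [swimmer_geometry()].
#' @param state,action integer n-tuples; the move must be available
#'   (see [is_valid_move()]).
#' @param params a [stokes_params()].
#' @param nodes quadrature order override (used for refinement checks).
#' @return scalar displacement, length units.
#' @export
move_displacement <- function(geom, state, action, params = stokes_params(),
                              nodes = params$quadrature_nodes) {
  if (!is_valid_move(geom, state, action)) {
    stop("unavailable state-action pair")
  }
  move_displacement_unchecked(geom, state, action, params, nodes)
}

move_displacement_unchecked <- function(geom, state, action, params,
                                        nodes = params$quadrature_nodes) {
  g <- gauss01(nodes)
  omega <- action * geom$theta_step
  r <- 0
  for (k in seq_along(g$nodes)) {
    th <- (state + action * g$nodes[k]) * geom$theta_step
    cl <- discretize(geom, th, omega)
    r <- r + g$weights[k] * swim_speed_fast(cl, params)
  }
  r
}

#' Instantaneous power exerted on the fluid
#'
#' Sum over points of `F . (U_P + U0)`, the rate of working of the swimmer on
#' the fluid at one instant; non-negative up to solver tolerance (viscous
#' dissipation).
#'
#' @param solve a [solve_swim()] result.
#' @param points the point cloud the solve was computed for.
#' @return scalar power.
#' @export
instantaneous_power <- function(solve, points) {
  u <- sweep(points$vel, 2, solve$swim_velocity, "+")
  sum(solve$forces * u)
}

#' Tow drag coefficient of a rigid configuration
#'
#' Solves the resistance problem `M F = U` with unit horizontal velocity
#' `U = (1, 0)` prescribed at every point of the frozen configuration; the
#' drag coefficient is `zeta = sum(F_x)` over the swimmer points.  Used,
#' averaged over the discrete states of a stroke cycle, as the drag scale of
#' the Lighthill efficiency.
#'
#' Steady towing in an unbounded two-dimensional Stokes flow is ill-posed
#' (the Stokes paradox: the log kernel makes net-force problems depend on an
#' arbitrary outer scale), so the swimmer is towed inside a stationary
#' circular tank whose wall points carry zero velocity.  The wall reaction
#' balances the tow force, which restores well-posedness; the drag then
#' depends logarithmically on the tank radius, so `zeta` (and the absolute
#' Lighthill efficiency built from it) is a documented convention --
#' efficiency comparisons between strokes are meaningful as orderings.
#'
#' @param points a rigid (zero deformation velocity) point cloud.
#' @param params a [stokes_params()].
#' @param tank_radius radius of the enclosing tank, length units.
#' @param tank_spacing wall discretization spacing, length units.
#' @return scalar drag coefficient, force per unit speed.
#' @export
tow_drag <- function(points, params = stokes_params(),
                     tank_radius = 25, tank_spacing = 0.5) {
  P <- nrow(points$pos)
  nw <- ceiling(2 * pi * tank_radius / tank_spacing)
  ang <- (seq_len(nw) - 0.5) * 2 * pi / nw
  wall <- cbind(tank_radius * cos(ang), tank_radius * sin(ang))
  M <- assemble_mobility_cpp(rbind(points$pos, wall),
                             params$mu, params$epsilon)
  b <- numeric(2 * (P + nw))
  b[seq(1, 2 * P, by = 2)] <- 1
  f <- solve(M, b)
  sum(f[seq(1, 2 * P, by = 2)])
}
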