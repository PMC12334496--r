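#' Construct the paddler geometry
#'
#' Defines the static shape of the swimmer: an elongated body of length 10
#' with semicircular end caps of radius 1, carrying `n_pairs` pairs of rigid
#' paddles of length 3 anchored on the top and bottom straight sections.
#' Anchors are equally spaced by `spacing` and centred on the body midpoint.
#' The body outline is discretized once at construction (points equally
#' spaced by at most `point_spacing` per component) and cached in the
#' returned object; paddle points are laid out per configuration by
#' [discretize()].
#'
#' The paddle tilt grid is `theta = s * theta_step` for integer states
#' `s` in `[-state_bound, state_bound]`, i.e. a maximum tilt of `pi/4`
#' from the perpendicular rest position.
#'
#' When `(n_pairs - 1) * spacing` exceeds the straight section
#' (`body_length - 2 * cap_radius`) the outer anchors are placed on the
#' extension of the straight-section line `y = +-cap_radius`, which keeps the
#' printed wide-spacing configurations constructible; the object records this
#' in `relaxed_layout` and every artifact echoes it.  Anchors beyond the body
#' ends (`|x| > body_length / 2`) are a configuration error.
#'
#' @param n_pairs number of paddle pairs (n >= 1).
#' @param spacing anchor spacing `d` along the body, length units.
#' @param body_length,cap_radius,paddle_length body dimensions, length units.
#' @param point_spacing maximum arc-length separation of discretization
#'   points, length units.
#' @param theta_step angular grid step, radians.
#' @param state_bound largest admissible `|s|`.
#' @return an object of class `swimmer_geometry`.
#' @seealso [discretize()], [anchor_positions()], [is_valid_state()]
#' @export
#' @examples
#' geom <- swimmer_geometry(2, 4)
#' anchor_positions(geom)
swimmer_geometry <- function(n_pairs, spacing,
                             body_length = 10, cap_radius = 1,
                             paddle_length = 3, point_spacing = 0.1,
                             theta_step = pi / 20, state_bound = 5L) {
  stopifnot(length(n_pairs) == 1L, n_pairs >= 1, n_pairs == round(n_pairs),
            length(spacing) == 1L, spacing > 0,
            point_spacing > 0, theta_step > 0, state_bound >= 1)
  if (abs(theta_step * state_bound - pi / 4) > 1e-12) {
    stop("theta_step * state_bound must equal pi/4 (maximum tilt)")
  }
  n_pairs <- as.integer(n_pairs)
  half <- body_length / 2
  xa <- anchor_x(n_pairs, spacing)
  if (max(abs(xa)) > half + 1e-12) {
    stop("configuration error: anchors extend beyond the body ends ",
         "((n_pairs - 1) * spacing > body_length)")
  }
  relaxed <- max(abs(xa)) > half - cap_radius + 1e-12
  geom <- structure(
    list(n_pairs = n_pairs, spacing = spacing,
         body_length = body_length, cap_radius = cap_radius,
         paddle_length = paddle_length, point_spacing = point_spacing,
         theta_step = theta_step, state_bound = as.integer(state_bound),
         relaxed_layout = relaxed),
    class = "swimmer_geometry")
  geom$body <- build_body(geom, xa)
  geom
}

anchor_x <- function(n, d) -(n - 1) * d / 2 + (seq_len(n) - 1) * d

#' @export
print.swimmer_geometry <- function(x, ...) {
  cat(sprintf(
    "<swimmer_geometry> %d paddle pair(s), spacing %g, body %g, caps %g\n",
    x$n_pairs, x$spacing, x$body_length, x$cap_radius))
  cat(sprintf("  point spacing %g, theta grid %d steps of %.4f rad%s\n",
              x$point_spacing, 2L * x$state_bound + 1L, x$theta_step,
              if (x$relaxed_layout) " [relaxed anchor layout]" else ""))
  invisible(x)
}

# Discretize the (theta-independent) body outline: the top straight section,
# the top halves of the two caps, and the on-axis cap tips.  The bottom half
# is always produced by mirroring so the cloud is exactly symmetric in y.
# Straight-section points sit on a half-offset grid so that the common
# integer/half-integer anchor abscissae never coincide with a body point; any
# residual coincidence (possible for particular spacings) is resolved by
# nudging the offending body point by half the local spacing, which locally
# allows a gap of 1.5 * point_spacing.
build_body <- function(geom, xa) {
  h <- geom$point_spacing
  r <- geom$cap_radius
  Ls <- geom$body_length - 2 * r
  xr <- Ls / 2                             # straight section on [-xr, xr]
  m <- ceiling(Ls / h)
  ds <- Ls / m
  x_str <- -xr + (seq_len(m) - 0.5) * ds   # no corner points
  mc <- ceiling(pi * r / h)
  dphi <- pi / mc
  phi <- pi / 2 - (0:mc) * dphi            # cap parameter, pi/2 .. -pi/2
  phi_top <- phi[phi > 1e-12]              # includes the corners y = r
  has_axis <- any(abs(phi) < 1e-12)

  cap_r <- cbind(xr + r * cos(phi_top), r * sin(phi_top))
  cap_l <- cbind(-xr - r * cos(phi_top), r * sin(phi_top))
  top <- rbind(cbind(x_str, r), cap_r, cap_l)
  kind <- c(rep("straight", m), rep("cap_r", nrow(cap_r)),
            rep("cap_l", nrow(cap_l)))

  # resolve body points coinciding with a paddle anchor (x_a, r)
  for (x0 in xa) {
    hit <- which(abs(top[, 2] - r) < 1e-9 & abs(top[, 1] - x0) < 1e-6)
    for (i in hit) {
      if (kind[i] == "straight") {
        top[i, 1] <- top[i, 1] - sign(top[i, 1] + 1e-15) * ds / 2
      } else {                             # cap corner: rotate along the arc
        s <- if (kind[i] == "cap_r") 1 else -1
        ang <- pi / 2 - dphi / 2
        top[i, ] <- c(s * xr + s * r * cos(ang), r * sin(ang))
      }
    }
  }
  axis_pts <- if (has_axis) {
    rbind(c(xr + r, 0), c(-xr - r, 0))
  } else {
    matrix(numeric(0), ncol = 2)
  }
  dimnames(top) <- NULL
  dimnames(axis_pts) <- NULL
  list(top = top, axis = axis_pts, anchors_x = xa,
       ds = ds, dphi = dphi)
}

#' Map an integer paddle state to a tilt angle
#'
#' @param s integer state(s) in `[-state_bound, state_bound]`.
#' @param geom a [swimmer_geometry()]; defaults supply the standard
#'   `pi/20` grid with bound 5.
#' @return `theta = s * theta_step`, radians.
#' @export
angle_from_state <- function(s, geom = NULL) {
  step <- if (is.null(geom)) pi / 20 else geom$theta_step
  bound <- if (is.null(geom)) 5L else geom$state_bound
  if (any(s != round(s)) || any(abs(s) > bound)) {
    stop("state out of range: |s| must be an integer <= ", bound)
  }
  s * step
}

#' Paddle pair orientation for a tilt angle
#'
#' The top and bottom paddles of a pair beat mirror-symmetrically about the
#' body axis: `psi_bottom = -pi/2 + theta`, `psi_top = pi/2 - theta`, with
#' `theta = 0` the perpendicular rest pose and positive `theta` tilting both
#' paddles toward the front (+x).
#'
#' @param theta tilt from perpendicular, radians, `|theta| <= pi/4`.
#' @return list with `theta`, `psi_top`, `psi_bottom` (radians).
#' @export
paddle_pose <- function(theta) {
  if (any(abs(theta) > pi / 4 + 1e-12)) {
    stop("|theta| must not exceed pi/4")
  }
  list(theta = theta, psi_top = pi / 2 - theta, psi_bottom = -pi / 2 + theta)
}

#' Anchor abscissae of the paddle array
#'
#' Anchors are equally spaced and centred on the body midpoint:
#' `x_j = -(n-1) d / 2 + (j-1) d`, duplicated at `y = +-cap_radius`.
#' Index j increases toward the front (+x), so paddle `n` is the frontmost.
#'
#' @param geom a [swimmer_geometry()].
#' @return numeric vector of anchor x coordinates, rearmost first.
#' @export
anchor_positions <- function(geom) {
  stopifnot(inherits(geom, "swimmer_geometry"))
  geom$body$anchors_x
}

#' Discretize the swimmer at a paddle configuration
#'
#' Produces the point cloud used by the mobility solver: the body outline
#' (zero deformation velocity) plus `2 n` paddle segments emanating outward
#' from the anchors at angles given by [paddle_pose()].  Paddle point
#' velocities are rigid rotations about the anchor with tilt rate
#' `omega_j = dtheta_j/dt`; the bottom paddle rotates oppositely to the top
#' one so the pair stays mirror-symmetric and the prescribed net y-momentum
#' vanishes.
#'
#' Points are ordered `[top half, on-axis cap tips, bottom half]` with the
#' bottom half the exact y-mirror of the top half in the same order, an
#' invariant the symmetric fast solver relies on.
#'
#' @param geom a [swimmer_geometry()].
#' @param thetas tilt angle per paddle, radians (length `n_pairs`).
#' @param omega tilt rate per paddle, radians/time (length `n_pairs`).
#' @return an object of class `point_cloud`: `pos` and `vel` (P x 2
#'   matrices), `label` (per-point component tag), `n_top`, `n_axis`, and the
#'   anchor coordinates.
#' @export
discretize <- function(geom, thetas, omega = numeric(geom$n_pairs)) {
  stopifnot(inherits(geom, "swimmer_geometry"),
            length(thetas) == geom$n_pairs, length(omega) == geom$n_pairs)
  if (any(abs(thetas) > pi / 4 + 1e-9)) {
    stop("|theta| must not exceed pi/4")
  }
  body <- geom$body
  mp <- ceiling(geom$paddle_length / geom$point_spacing)
  ell <- (0:mp) * (geom$paddle_length / mp)
  n <- geom$n_pairs
  pad_pos <- vector("list", n)
  pad_vel <- vector("list", n)
  for (j in seq_len(n)) {
    dirx <- sin(thetas[j]); diry <- cos(thetas[j])
    pad_pos[[j]] <- cbind(body$anchors_x[j] + ell * dirx,
                          geom$cap_radius + ell * diry)
    pad_vel[[j]] <- cbind(ell * omega[j] * diry, -ell * omega[j] * dirx)
  }
  top_pos <- rbind(body$top, do.call(rbind, pad_pos))
  top_vel <- rbind(matrix(0, nrow(body$top), 2), do.call(rbind, pad_vel))
  n_axis <- nrow(body$axis)
  mirror <- function(m) cbind(m[, 1], -m[, 2])
  pos <- rbind(top_pos, body$axis, mirror(top_pos))
  vel <- rbind(top_vel, matrix(0, n_axis, 2), mirror(top_vel))
  dimnames(pos) <- NULL
  dimnames(vel) <- NULL
  lab_top <- c(rep("body", nrow(body$top)),
               rep(paste0("paddle", seq_len(n), "_top"), each = mp + 1L))
  label <- c(lab_top, rep("body", n_axis),
             sub("_top$", "_bottom", lab_top))
  structure(list(pos = pos, vel = vel, label = label,
                 n_top = nrow(top_pos), n_axis = n_axis,
                 anchors_x = body$anchors_x, geom = geom),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points (%d per half, %d on axis)\n",
              nrow(x$pos), x$n_top, x$n_axis))
  invisible(x)
}

# top-side paddle segments (anchor, tip) for a continuous configuration
paddle_segments <- function(geom, thetas) {
  xa <- geom$body$anchors_x
  list(ax = xa, ay = rep(geom$cap_radius, length(xa)),
       bx = xa + geom$paddle_length * sin(thetas),
       by = geom$cap_radius + geom$paddle_length * cos(thetas))
}

# strict proper intersection of open segments (touching does not count)
segments_cross <- function(ax1, ay1, bx1, by1, ax2, ay2, bx2, by2) {
  crs <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- crs(ax1, ay1, bx1, by1, ax2, ay2)
  d2 <- crs(ax1, ay1, bx1, by1, bx2, by2)
  d3 <- crs(ax2, ay2, bx2, by2, ax1, ay1)
  d4 <- crs(ax2, ay2, bx2, by2, bx1, by1)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

config_collides <- function(geom, thetas) {
  n <- geom$n_pairs
  if (n < 2L) return(FALSE)
  s <- paddle_segments(geom, thetas)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      if (segments_cross(s$ax[j], s$ay[j], s$bx[j], s$by[j],
                         s$ax[k], s$ay[k], s$bx[k], s$by[k])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Geometric availability of states and moves
#'
#' A state is valid iff no two same-side paddle segments properly intersect
#' (open segments; the anchors are always distinct).  A move is valid iff the
#' action moves at least one paddle, no coordinate leaves the state bounds,
#' and the configuration is collision-free at both endpoints and at the three
#' interior Gauss-Legendre quadrature times of the unit move interval -- the
#' same instants at which the displacement reward is evaluated.
#'
#' @param geom a [swimmer_geometry()].
#' @param state integer n-tuple of paddle states.
#' @param action integer n-tuple in `{-1, 0, 1}`.
#' @return logical scalar.
#' @export
is_valid_state <- function(geom, state) {
  stopifnot(length(state) == geom$n_pairs)
  if (any(state != round(state)) || any(abs(state) > geom$state_bound)) {
    return(FALSE)
  }
  !config_collides(geom, state * geom$theta_step)
}

#' @rdname is_valid_state
#' @export
is_valid_move <- function(geom, state, action) {
  stopifnot(length(action) == geom$n_pairs)
  if (all(action == 0)) return(FALSE)
  if (!all(action %in% c(-1, 0, 1))) return(FALSE)
  nxt <- state + action
  if (any(abs(nxt) > geom$state_bound)) return(FALSE)
  if (!is_valid_state(geom, state) || !is_valid_state(geom, nxt)) {
    return(FALSE)
  }
  for (t in gauss01(3L)$nodes) {
    if (config_collides(geom, (state + action * t) * geom$theta_step)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Mirror a configuration or action front-to-back
#'
#' The reflection `x -> -x` maps paddle `j` to paddle `n + 1 - j` and negates
#' every tilt, i.e. `(s_1, ..., s_n) -> (-s_n, ..., -s_1)`.  Validity is
#' invariant under this map and move rewards are antisymmetric.
#'
#' @param s integer n-tuple (state or action).
#' @return the mirrored tuple.
#' @export
mirror_state <- function(s) rev(-s)

#' @rdname mirror_state
#' @export
mirror_action <- function(a) rev(-a)
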