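test_that("state-to-angle map covers the pi/20 grid and rejects out-of-range states", {
  expect_identical(angle_from_state(0), 0)
  expect_equal(angle_from_state(5), pi / 4)
  expect_equal(angle_from_state(-3), -3 * pi / 20)
  expect_equal(angle_from_state(-5:5), (-5:5) * pi / 20)
  expect_error(angle_from_state(6), "out of range")
  expect_error(angle_from_state(0.5), "out of range")
})

test_that("paddle pose keeps the pair mirror-symmetric about the body axis", {
  p <- paddle_pose(0)
  expect_equal(p$psi_bottom, -pi / 2)
  expect_equal(p$psi_top, pi / 2)
  expect_equal(paddle_pose(pi / 4)$psi_bottom, -pi / 4)
  expect_equal(paddle_pose(pi / 4)$psi_top, pi / 4)
  expect_equal(paddle_pose(-pi / 4)$psi_bottom, -3 * pi / 4)
  expect_equal(paddle_pose(-pi / 4)$psi_top, 3 * pi / 4)
  th <- seq(-pi / 4, pi / 4, length.out = 11)
  expect_equal(paddle_pose(th)$psi_bottom, -paddle_pose(th)$psi_top)
  expect_error(paddle_pose(pi / 3), "pi/4")
})

test_that("anchors are centred on the body and wide layouts are handled", {
  expect_equal(anchor_positions(swimmer_geometry(2, 4)), c(-2, 2))
  expect_equal(anchor_positions(swimmer_geometry(3, 1)), c(-1, 0, 1))
  expect_false(swimmer_geometry(3, 1)$relaxed_layout)
  # anchors past the cap tangent points sit on the extended y = +-1 line
  g <- swimmer_geometry(4, 3.25)
  expect_equal(anchor_positions(g), c(-4.875, -1.625, 1.625, 4.875))
  expect_true(g$relaxed_layout)
  # but anchors beyond the body ends are a configuration error
  expect_error(swimmer_geometry(4, 4), "beyond the body")
})

test_that("discretization covers body and paddles at the prescribed spacing", {
  geom <- swimmer_geometry(2, 4)
  cl <- discretize(geom, c(0, 0))
  # perpendicular pose: top paddle 1 runs straight from (x_1, 1) to (x_1, 4)
  idx <- cl$label == "paddle1_top"
  expect_equal(sum(idx), 31L)
  expect_equal(range(cl$pos[idx, 2]), c(1, 4))
  expect_true(all(abs(cl$pos[idx, 1] - (-2)) < 1e-12))
  expect_true(all(cl$vel == 0))
  # adjacent points along each component never exceed the spacing bound
  # (locally 1.5x where a body point was nudged off an anchor); the closed
  # body outline is ordered by the polar angle about the body centre
  for (lab in unique(cl$label)) {
    pts <- cl$pos[cl$label == lab, , drop = FALSE]
    o <- if (lab == "body") {
      order(atan2(pts[, 2] / geom$cap_radius,
                  pts[, 1] / (geom$body_length / 2)))
    } else {
      order(pts[, 1], pts[, 2])
    }
    pts <- pts[o, , drop = FALSE]
    if (lab == "body") pts <- rbind(pts, pts[1, ])   # close the loop
    gaps <- sqrt(rowSums(diff(pts)^2))
    expect_lt(max(gaps), 1.5 * geom$point_spacing + 1e-9)
  }
  # no two points coincide
  expect_gt(min(dist(cl$pos)), 1e-6)
})

test_that("paddle velocities are rigid rotations with mirror symmetry", {
  geom <- swimmer_geometry(2, 4)
  cl <- discretize(geom, c(0.3, -0.2), c(pi / 20, -pi / 30))
  nt <- cl$n_top; na <- cl$n_axis
  bot <- cl$pos[nt + na + seq_len(nt), ]
  expect_equal(bot, cbind(cl$pos[1:nt, 1], -cl$pos[1:nt, 2]))
  botv <- cl$vel[nt + na + seq_len(nt), ]
  expect_equal(botv, cbind(cl$vel[1:nt, 1], -cl$vel[1:nt, 2]))
  # body points never deform
  expect_true(all(cl$vel[cl$label == "body", ] == 0))
  # pair-wise prescribed y-momentum vanishes
  for (j in 1:2) {
    sel <- grepl(sprintf("paddle%d_", j), cl$label)
    expect_equal(sum(cl$vel[sel, 2]), 0)
  }
  # tip speed equals paddle_length * |omega|
  cl2 <- discretize(geom, c(0, 0), c(pi / 20, 0))
  tip <- which.max(cl2$pos[cl2$label == "paddle1_top", 2])
  vtip <- cl2$vel[cl2$label == "paddle1_top", ][tip, ]
  expect_equal(sqrt(sum(vtip^2)), 3 * pi / 20)
})

test_that("reflecting the swimmer front-to-back mirrors the point cloud exactly", {
  geom <- swimmer_geometry(3, 1.5)
  set.seed(11)
  for (rep in 1:5) {
    s <- sample(-5:5, 3, replace = TRUE)
    a <- sample(-1:1, 3, replace = TRUE)
    cl <- discretize(geom, s * pi / 20, a * pi / 20)
    clm <- discretize(geom, rev(-s) * pi / 20, rev(-a) * pi / 20)
    key <- function(m) m[order(round(m[, 1], 9), round(m[, 2], 9)), ]
    expect_equal(key(cbind(-cl$pos[, 1], cl$pos[, 2])), key(clm$pos))
  }
})

test_that("state validity matches open-segment collision geometry", {
  g5 <- swimmer_geometry(2, 5)
  # at spacing 5 the paddles can never reach each other: all 121 states valid
  grid <- as.matrix(expand.grid(-5:5, -5:5))
  expect_true(all(apply(grid, 1, function(s) is_valid_state(g5, s))))
  # at spacing 4, only the fully tilted-in corner state collides
  g4 <- swimmer_geometry(2, 4)
  expect_false(is_valid_state(g4, c(5, -5)))
  expect_true(is_valid_state(g4, c(-5, 5)))   # tilted away: fine
  expect_true(is_valid_state(g4, c(5, -4)))
  # validity is reflection-invariant
  g1 <- swimmer_geometry(2, 0.75)
  set.seed(7)
  for (rep in 1:50) {
    s <- sample(-5:5, 2, replace = TRUE)
    expect_identical(is_valid_state(g1, s), is_valid_state(g1, mirror_state(s)))
  }
})

test_that("move availability enforces motion, bounds, and swept collisions", {
  g <- swimmer_geometry(2, 5)
  expect_false(is_valid_move(g, c(0, 0), c(0, 0)))
  expect_false(is_valid_move(g, c(5, 0), c(1, 0)))
  expect_true(is_valid_move(g, c(5, 0), c(-1, 1)))
  g4 <- swimmer_geometry(2, 4)
  expect_false(is_valid_move(g4, c(4, -4), c(1, -1)))  # would enter collision
  expect_true(is_valid_move(g4, c(4, -4), c(-1, 1)))
})
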