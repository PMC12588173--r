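test_that("axis recovery on a noiseless helix is within 0.5 degrees", {
  for (turns in c(1.5, 2, 3)) {
    hx <- make_helix(radius = 3, pitch = 2, turns = turns,
                     samples_per_turn = 360)
    cl <- centerline3d(hx$points)
    fr <- fit_modiolar_axis(cl, rw_center = hx$points[1, ])
    expect_lt(angle_between_deg(fr$axis_dir, c(0, 0, 1)), 0.5)
    expect_lt(dist_to_axis(fr$axis_point, c(0, 0, 0), c(0, 0, 1)), 0.05)
  }
})

test_that("axis recovery is equivariant under rigid rotation", {
  hx <- make_helix(radius = 3, pitch = 2, turns = 2.5)
  R <- rotation_matrix(11)
  shift <- c(4, -7, 2)
  cl <- centerline3d(rigid_transform(hx$points, R, shift))
  fr <- fit_modiolar_axis(cl, rw_center = cl$points[1, ])
  expect_lt(angle_between_deg(fr$axis_dir, R %*% c(0, 0, 1)), 0.5)
})

test_that("a planar circle yields its normal as the axis", {
  th <- seq(0, 2 * pi, length.out = 181)
  cl <- centerline3d(cbind(2 + cos(th), -1 + sin(th), 5))
  fr <- fit_modiolar_axis(cl, rw_center = c(3.5, -1, 5))
  expect_lt(angle_between_deg(fr$axis_dir, c(0, 0, 1)), 0.5)
})

test_that("axis recovery with tracing noise stays within 2 degrees", {
  g <- generate_cochlea(cochlea_spec(noise_sd = 0.02, seed = 101))
  fr <- fit_modiolar_axis(g$bm, g$rw_center)
  expect_lt(angle_between_deg(fr$axis_dir, g$truth$axis_dir), 2)
})

test_that("frame invariants hold and degenerate inputs error", {
  g <- generate_cochlea(cochlea_spec())
  fr <- fit_modiolar_axis(g$bm, g$rw_center)
  expect_equal(sum(fr$axis_dir^2), 1, tolerance = 1e-9)
  expect_equal(sum(fr$zero_ray^2), 1, tolerance = 1e-9)
  expect_lt(abs(sum(fr$axis_dir * fr$zero_ray)), 1e-9)

  line <- centerline3d(cbind(seq(0, 5, by = 0.5), 0, 0))
  expect_error(fit_modiolar_axis(line, c(0, 1, 0)), "collinear")

  # round-window landmark on the axis: zero ray undefined
  expect_error(modiolar_frame(c(0, 0, 0), c(0, 0, 1), rw_center = c(0, 0, 3)),
               "zero ray")
})

test_that("angular depth starts at 0 on the zero ray and unwraps monotonically", {
  # helix sampled every quarter turn over 2.5 turns
  hx <- make_helix(radius = 2, pitch = 1, turns = 2.5, samples_per_turn = 4)
  cl <- centerline3d(hx$points)
  fr <- modiolar_frame(c(0, 0, 0), c(0, 0, 1), rw_center = hx$points[1, ])
  expect_equal(angular_depth(cl, fr), seq(0, 900, by = 90), tolerance = 1e-9)
})

test_that("angular depth is invariant under a joint rigid transform", {
  g <- generate_cochlea(cochlea_spec())
  fr <- modiolar_frame(g$truth$axis_point, g$truth$axis_dir, g$rw_center)
  a0 <- angular_depth(g$bm, fr)
  R <- rotation_matrix(3)
  shift <- c(-2, 8, 1)
  bm_t <- centerline3d(rigid_transform(g$bm$points, R, shift))
  fr_t <- modiolar_frame(drop(R %*% g$truth$axis_point) + shift,
                         drop(R %*% g$truth$axis_dir),
                         drop(R %*% g$rw_center) + shift)
  expect_equal(angular_depth(bm_t, fr_t), a0, tolerance = 1e-6)
})

test_that("points on the axis are reported, not skipped", {
  cl <- centerline3d(rbind(c(1, 0, 0), c(0, 0, 1e-12), c(-1, 0, 0.2)))
  fr <- modiolar_frame(c(0, 0, 0), c(0, 0, 1), rw_center = c(1, 0, 0))
  expect_error(angular_depth(cl, fr), "point\\(s\\) 2")
})

test_that("angle profiles of generated geometries are monotone with the generator angle", {
  for (seed in c(1, 5)) {
    noisy <- seed == 5
    g <- generate_cochlea(cochlea_spec(seed = seed,
                                       noise_sd = if (noisy) 0.005 else 0))
    fr <- fit_modiolar_axis(g$bm, g$rw_center)
    # with tracing noise, measure angles at 0.5 mm stations so forward
    # progress between samples dominates the jitter
    bm <- if (noisy) resample_centerline(g$bm$points, 0.5) else g$bm
    bm_ang <- angular_depth(bm, fr)
    expect_true(all(diff(bm_ang) >= -1e-9))
    expect_lt(abs(bm_ang[1]), 5)
    expect_equal(max(bm_ang), g$spec$bm_total_angle,
                 tolerance = 3 / g$spec$bm_total_angle)
  }
})
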