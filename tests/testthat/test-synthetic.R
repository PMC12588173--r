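test_that("the default specimen preset carries the calibrated dimensions", {
  spec <- cochlea_spec()
  expect_equal(sum(spec$turn_lengths), 34.10)
  expect_equal(spec$sg_total_length, 14.73)
  expect_equal(spec$rotation_onset_deg, 650)
  expect_equal(spec$bm_total_angle, 1040)
  expect_equal(spec$sg_total_angle, 720)
})

test_that("generated geometry hits the requested lengths and angles", {
  g <- generate_cochlea(cochlea_spec())
  expect_equal(total_length(g$bm), 34.10, tolerance = 0.03 / 34.10)
  expect_equal(total_length(g$sg), 14.73, tolerance = 0.015 / 14.73)
  fr <- modiolar_frame(g$truth$axis_point, g$truth$axis_dir, g$rw_center)
  expect_equal(max(angular_depth(g$bm, fr)), 1040, tolerance = 2 / 1040)
  expect_equal(max(angular_depth(g$sg, fr)), 720, tolerance = 2 / 720)
})

test_that("identical seeds give bit-identical output", {
  a <- generate_cochlea(cochlea_spec(noise_sd = 0.01, seed = 9))
  b <- generate_cochlea(cochlea_spec(noise_sd = 0.01, seed = 9))
  expect_identical(a$bm$points, b$bm$points)
  expect_identical(a$sg$points, b$sg$points)
  expect_identical(lapply(a$dendrites, `[[`, "points"),
                   lapply(b$dendrites, `[[`, "points"))
})

test_that("noiseless dendrite endpoints lie exactly on their centerlines", {
  g <- generate_cochlea(cochlea_spec())
  bm_rows <- do.call(rbind, lapply(g$dendrites, function(d) d$points[1, ]))
  sg_rows <- do.call(rbind, lapply(g$dendrites, function(d)
    d$points[nrow(d$points), ]))
  on_line <- function(rows, line) apply(rows, 1, function(p)
    min(sqrt(rowSums(sweep(line$points, 2, p)^2))))
  expect_true(all(on_line(bm_rows, g$bm) == 0))
  expect_true(all(on_line(sg_rows, g$sg) == 0))
})

test_that("unsatisfiable length/angle combinations raise a generation error", {
  expect_error(
    generate_cochlea(cochlea_spec(bm_total_length = 200,
                                  turn_lengths = c(100, 60, 40))),
    "cannot reach")
  expect_error(cochlea_spec(turn_lengths = c(1, 2, 3)), "sum")
  expect_error(cochlea_spec(sg_total_angle = 2000), "exceed")
})

test_that("full pipeline on the preset recovers axis, truth map, and divergence", {
  g <- generate_cochlea(cochlea_spec())
  fit <- cochlear_tonotopy(g$bm, g$sg, g$dendrites, g$rw_center)

  # fitted axis within 0.5 degrees of the generator's
  expect_lt(angle_between_deg(fit$frame$axis_dir, g$truth$axis_dir), 0.5)

  # OC frequencies equal the generator's ground truth
  expect_equal(fit$oc_map$freq_hz, g$truth$bm_freq, tolerance = 1e-9)

  # OC and SG angle-frequency curves coincide below the rotation onset
  onset <- g$spec$rotation_onset_deg
  sgm <- fit$sg_map
  basal <- sgm[sgm$angle_deg <= onset - 1, ]
  oc_at <- exp(stats::approx(fit$oc_map$angle_deg, log(fit$oc_map$freq_hz),
                             xout = basal$angle_deg)$y)
  expect_lt(max(semitone_difference(basal$freq_hz, oc_at)), 1)

  # ... and diverge beyond it: the apical-most SG records carry frequencies
  # far below the OC at the same angle (spatial compression)
  apical <- sgm[sgm$angle_deg > onset + 20, ]
  oc_ap <- exp(stats::approx(fit$oc_map$angle_deg, log(fit$oc_map$freq_hz),
                             xout = apical$angle_deg)$y)
  expect_gt(max(semitone_difference(apical$freq_hz, oc_ap)), 12)

  # SG terminal angle 720 +- 2
  expect_equal(fit$sg_angle_deg, 720, tolerance = 2 / 720)
})

test_that("Greenwood parameters are recovered from the generated OC map", {
  g <- generate_cochlea(cochlea_spec())
  fr <- modiolar_frame(g$truth$axis_point, g$truth$axis_dir, g$rw_center)
  oc <- map_oc_frequencies(g$bm, angular_depth(g$bm, fr))
  idx <- round(seq(1, nrow(oc), length.out = 40))
  fit <- fit_greenwood(oc$x[idx], oc$freq_hz[idx],
                       init = greenwood_params(100, 1.5, 0.5))
  expect_equal(unname(coef(fit)), c(165.4, 2.1, 0.88), tolerance = 1e-3)
})
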