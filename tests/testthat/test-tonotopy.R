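oc_line_map <- function(s, L = max(s), angles = NULL) {
  if (is.null(angles)) angles <- s / max(s) * 1000
  bm <- centerline3d(cbind(s, 0, 0))
  map_oc_frequencies(bm, angles)
}

test_that("OC mapping assigns turn-end frequencies from proportional length", {
  map <- oc_line_map(c(0, 21.38, 29.75, 34.10))
  expect_equal(round(map$freq_hz[2]), 859)
  expect_equal(round(map$freq_hz[3]), 161)
  expect_equal(map$freq_hz[4], greenwood_forward(0))
  expect_true(all(diff(map$freq_hz) < 0))
  expect_true(all(map$x >= 0 & map$x <= 1))
})

test_that("semitone differences reproduce the reference 90-degree table", {
  tab <- reference_frequency_table()
  ok <- !is.na(tab$sg_hz)
  got <- round(semitone_difference(tab$oc_hz[ok], tab$sg_hz[ok]), 1)
  expect_equal(got, c(0.1, 0.6, 0.4, 0.3, 0.0, 2.0, 1.3, 3.3, 35.1))
})

test_that("semitone difference satisfies identity and octave axioms", {
  expect_equal(semitone_difference(440, 440), 0)
  expect_equal(semitone_difference(880, 440), 12)
  expect_equal(semitone_difference(440, 880), 12)  # absolute
  expect_error(semitone_difference(-1, 100), "positive")
  expect_error(semitone_difference(100, 0), "positive")
})

test_that("dendrite transfer conserves traces, sorts, and merges duplicates", {
  s_bm <- seq(0, 10, by = 1)
  oc <- oc_line_map(s_bm)
  bm <- centerline3d(cbind(s_bm, 0, 0))
  sg <- centerline3d(cbind(seq(0, 5, by = 1), 1, 0), label = "SG")
  sg_ang <- seq(0, 50, by = 10)
  den <- function(xb, xs) dendrite_trace(rbind(c(xb, 0, 0), c(xs, 1, 0)),
                                         bm_attach = xb, sg_attach = xs)

  # 5 distinct dendrites in -> 5 records out, sorted by SG arc position
  d5 <- list(den(9, 5), den(2, 1), den(6, 3), den(4, 2), den(8, 4))
  out <- transfer_to_sg(oc, d5, sg, sg_ang, bm = bm)
  expect_equal(nrow(out), 5L)
  expect_true(all(diff(out$s_mm) > 0))
  expect_identical(attr(out, "structure"), "SG")

  # coincident SG attachments merge as a geometric mean
  d3 <- list(den(2, 1), den(4, 1), den(6, 3))
  out2 <- transfer_to_sg(oc, d3, sg, sg_ang, bm = bm)
  expect_equal(nrow(out2), 2L)
  f2 <- stats::approx(oc$s_mm, log(oc$freq_hz), xout = c(2, 4))$y
  expect_equal(out2$freq_hz[1], exp(mean(f2)), tolerance = 1e-9)

  # endpoint off the SG centerline is an attachment error naming the trace
  bad <- list(den(2, 1),
              dendrite_trace(rbind(c(4, 0, 0), c(2, 1.7, 0)),
                             bm_attach = 4, sg_attach = 2))
  expect_error(transfer_to_sg(oc, bad, sg, sg_ang, bm = bm), "dendrite 2")
  expect_error(transfer_to_sg(oc, d5[1], sg, sg_ang), "at least 2")
})

test_that("radial dendrites make SG frequencies match OC at equal angles", {
  g <- generate_cochlea(cochlea_spec())
  fr <- modiolar_frame(g$truth$axis_point, g$truth$axis_dir, g$rw_center)
  oc <- map_oc_frequencies(g$bm, angular_depth(g$bm, fr))
  sgm <- transfer_to_sg(oc, g$dendrites, g$sg, angular_depth(g$sg, fr),
                        bm = g$bm)
  onset <- g$spec$rotation_onset_deg
  basal <- sgm[sgm$angle_deg <= onset - 1, ]
  oc_at <- exp(stats::approx(oc$angle_deg, log(oc$freq_hz),
                             xout = basal$angle_deg)$y)
  expect_true(all(abs(basal$freq_hz / oc_at - 1) < 0.005))

  # beyond the rotation onset the SG stays within its angular span
  expect_lte(max(sgm$angle_deg), g$spec$sg_total_angle + 2)
  expect_gt(max(oc$angle_deg), 1038)
})

test_that("rate of change recovers the constant slope of an exponential map", {
  s <- seq(0, 10, by = 0.1)
  map <- tonotopic_map(s, (10 - s) / 10, 10 * s, 1000 * 2^(-s / 2))
  rp <- rate_of_change(map, axis = "length")
  expect_true(all(abs(rp$rate - 6) < 0.06))  # 12 / 2 semitones per mm
  expect_identical(attr(rp, "unit"), "semitones/mm")
  rp_a <- rate_of_change(map, axis = "angle")
  expect_true(all(abs(rp_a$rate - 0.6) < 0.006))

  flat <- tonotopic_map(s, (10 - s) / 10, 10 * s, rep(500, length(s)))
  expect_true(all(rate_of_change(flat, axis = "length")$rate == 0))

  wiggly <- tonotopic_map(c(0, 1, 0.5), c(1, 0.5, 0.75), c(0, 10, 5),
                          c(100, 50, 75))
  expect_error(rate_of_change(wiggly, axis = "length"), "monotone")
})

test_that("basal OC rate from the reference table is 0.1 semitones/degree", {
  tab <- reference_frequency_table()
  x <- greenwood_inverse(tab$oc_hz)
  map <- tonotopic_map((1 - x) * 34.10, x, tab$angle_deg, tab$oc_hz)
  rp <- rate_of_change(map, axis = "angle", smoothing_window = 0)
  basal <- rp$rate[rp$position >= 90 & rp$position <= 450]
  expect_equal(round(mean(basal), 1), 0.1)
})

test_that("octave bands count, order, conserve span, and mirror", {
  s <- seq(0, 10, by = 0.01)
  map <- tonotopic_map(s, (10 - s) / 10, 100 * s, 20480 * 2^(-s))
  b <- octave_bands(map, ref_hz = 20)
  expect_equal(nrow(b), 11L)
  expect_equal(b$freq_hz, 20 * 2^(0:10))
  expect_true(all(diff(b$freq_hz) > 0))
  expect_true(all(diff(b$s_mm) < 0))
  # adjacent-band semitone spans sum to the map's total span
  spans <- semitone_difference(b$freq_hz[-1], b$freq_hz[-nrow(b)])
  expect_equal(sum(spans), 12 * log2(max(map$freq_hz) / min(map$freq_hz)),
               tolerance = 1e-9)

  # reversed orientation: same frequencies, mirrored positions
  rev_map <- tonotopic_map(10 - rev(s), rev((10 - s) / 10),
                           1000 - rev(100 * s), rev(20480 * 2^(-s)))
  b2 <- octave_bands(rev_map, ref_hz = 20)
  expect_equal(b2$freq_hz, b$freq_hz)
  expect_equal(b2$s_mm, 10 - b$s_mm, tolerance = 1e-9)

  expect_error(octave_bands(map, ref_hz = 5), "range")
})

test_that("octave-band positions round-trip through the Greenwood inverse", {
  g <- generate_cochlea(cochlea_spec())
  fr <- modiolar_frame(g$truth$axis_point, g$truth$axis_dir, g$rw_center)
  oc <- map_oc_frequencies(g$bm, angular_depth(g$bm, fr))
  b <- octave_bands(oc, ref_hz = 40)
  L <- max(oc$s_mm)
  expect_equal((L - b$s_mm) / L, greenwood_inverse(b$freq_hz),
               tolerance = 1e-6)
})
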