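# geometry fixtures built in code

# circular helix about the z axis, radius r, axial rise `pitch` per turn
make_helix <- function(radius = 3, pitch = 2, turns = 2.5,
                       samples_per_turn = 360) {
  th_deg <- seq(0, turns * 360, by = 360 / samples_per_turn)
  th <- th_deg * pi / 180
  list(points = cbind(radius * cos(th), radius * sin(th),
                      pitch * th_deg / 360),
       angles = th_deg)
}

# deterministic proper rotation matrix
rotation_matrix <- function(seed = 42) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_transform <- function(points, R, shift) {
  sweep(points %*% t(R), 2, shift, `+`)
}

angle_between_deg <- function(u, v) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u * u) * sum(v * v))
  acos(min(1, cosang)) * 180 / pi
}

# distance from a point to the line through p0 with direction d
dist_to_axis <- function(p, p0, d) {
  d <- d / sqrt(sum(d * d))
  rel <- p - p0
  rej <- rel - sum(rel * d) * d
  sqrt(sum(rej * rej))
}

# Reference specimen's OC and SG frequency summary at 90-degree increments
# (frequencies in Hz; SG absent beyond 720 degrees)
reference_frequency_table <- function() {
  data.frame(
    angle_deg = seq(0, 990, by = 90),
    oc_hz = c(13876, 4951, 2590, 1493, 832, 519, 363, 245, 152, 91, 52, 26),
    sg_hz = c(13996, 5119, 2645, 1467, 834, 463, 336, 202, 20, NA, NA, NA)
  )
}
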