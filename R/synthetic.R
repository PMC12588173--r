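#' Parameters of the synthetic cochlear-geometry generator
#'
#' Defines a parametric cochlea: a conical-helix basilar-membrane (BM)
#' centerline about the z axis, an inner spiral-ganglion (SG) helix, and
#' radial peripheral dendrites that rotate clockwise apically. The defaults
#' are the dimensions of the adult human left-ear specimen the package's
#' analyses are calibrated against: BM 34.10 mm over 1040 degrees (turn
#' lengths 21.38, 8.37, 4.35 mm), SG 14.73 mm over 720 degrees, apical
#' dendrite rotation starting at 650 degrees.
#'
#' The base radius and pitch are free (plausible human dimensions by
#' default); the radius-decay rate of each helix is solved numerically so
#' that the generated arc length matches the requested total. Printed turn
#' lengths are carried as metadata and are not individually enforced by the
#' helix shape (only total length and angular span are).
#'
#' @param bm_total_length total BM curvilinear length, mm.
#' @param bm_total_angle BM angular span, degrees.
#' @param turn_lengths per-turn BM lengths, mm; must sum to
#'   `bm_total_length`.
#' @param sg_total_length total SG curvilinear length, mm.
#' @param sg_total_angle SG angular span, degrees (<= `bm_total_angle`).
#' @param base_radius BM helix radius at the base, mm.
#' @param pitch_per_turn BM axial rise per 360 degrees, mm.
#' @param sg_base_radius SG helix radius at the base, mm.
#' @param sg_pitch_per_turn SG axial rise per 360 degrees, mm.
#' @param dendrite_count number of dendrite traces to generate.
#' @param rotation_onset_deg BM angular depth (degrees) past which dendrites
#'   rotate clockwise toward the SG terminus.
#' @param noise_sd isotropic Gaussian coordinate noise, mm (0 = noiseless).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param points_per_degree sampling density of the generated centerlines.
#' @param greenwood a [greenwood_params()] used for ground-truth frequencies.
#' @return An object of class `cochlea_spec`.
#' @seealso [generate_cochlea()]
#' @export
cochlea_spec <- function(bm_total_length = 34.10,
                         bm_total_angle = 1040,
                         turn_lengths = c(21.38, 8.37, 4.35),
                         sg_total_length = 14.73,
                         sg_total_angle = 720,
                         base_radius = 4.2,
                         pitch_per_turn = 2.0,
                         sg_base_radius = 2.0,
                         sg_pitch_per_turn = 1.0,
                         dendrite_count = 80L,
                         rotation_onset_deg = 650,
                         noise_sd = 0,
                         seed = 1L,
                         points_per_degree = 2,
                         greenwood = greenwood_params()) {
  stopifnot(bm_total_length > 0, bm_total_angle > 0, sg_total_length > 0,
            sg_total_angle > 0, base_radius > 0, pitch_per_turn > 0,
            sg_base_radius > 0, sg_pitch_per_turn > 0,
            dendrite_count >= 2, rotation_onset_deg > 0, noise_sd >= 0,
            points_per_degree > 0)
  if (abs(sum(turn_lengths) - bm_total_length) > 1e-6)
    stop("turn_lengths must sum to bm_total_length", call. = FALSE)
  if (sg_total_angle > bm_total_angle)
    stop("sg_total_angle cannot exceed bm_total_angle", call. = FALSE)
  if (rotation_onset_deg >= sg_total_angle)
    stop("rotation_onset_deg must lie below sg_total_angle", call. = FALSE)
  structure(list(
    bm_total_length = bm_total_length, bm_total_angle = bm_total_angle,
    turn_lengths = turn_lengths, sg_total_length = sg_total_length,
    sg_total_angle = sg_total_angle, base_radius = base_radius,
    pitch_per_turn = pitch_per_turn, sg_base_radius = sg_base_radius,
    sg_pitch_per_turn = sg_pitch_per_turn,
    dendrite_count = as.integer(dendrite_count),
    rotation_onset_deg = rotation_onset_deg, noise_sd = noise_sd,
    seed = as.integer(seed), points_per_degree = points_per_degree,
    greenwood = greenwood
  ), class = "cochlea_spec")
}

#' @export
print.cochlea_spec <- function(x, ...) {
  cat(sprintf(
    "<cochlea_spec> BM %.2f mm / %g deg; SG %.2f mm / %g deg; %d dendrites (rotation onset %g deg); noise sd %g mm; seed %d\n",
    x$bm_total_length, x$bm_total_angle, x$sg_total_length, x$sg_total_angle,
    x$dendrite_count, x$rotation_onset_deg, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic cochlear geometry with ground truth
#'
#' Builds the BM and SG centerlines, dendrite traces, the round-window-center
#' landmark (the BM's basal-most point), and the generator's ground truth
#' (axis, per-point angles, per-point frequencies). Each helix's exponential
#' radius-decay rate is solved by bisection so the arc length matches the
#' requested total to within 0.1%. Dendrites connect equal-angle BM/SG points
#' below `rotation_onset_deg`; beyond it, the SG attachment angle follows a
#' linear clockwise ramp that reaches the SG terminal angle at the BM apex.
#' With `noise_sd > 0`, i.i.d. Gaussian noise is added to every coordinate.
#'
#' @param spec a [cochlea_spec()].
#' @return An object of class `cochlea_geometry`: list with `bm`, `sg`
#'   ([centerline3d()]), `dendrites` (list of [dendrite_trace()]),
#'   `rw_center` (3D point), `truth` (list: `axis_point`, `axis_dir`,
#'   `bm_angles`, `sg_angles`, `bm_freq`, `dendrite_bm_angle`,
#'   `dendrite_sg_angle`, solved decay rates), and `spec`.
#' @examples
#' geom <- generate_cochlea(cochlea_spec())
#' total_length(geom$bm) # ~34.10
#' @export
generate_cochlea <- function(spec = cochlea_spec()) {
  stopifnot(inherits(spec, "cochlea_spec"))
  set.seed(spec$seed)

  bm_h <- solve_helix(spec$bm_total_length, spec$bm_total_angle,
                      spec$base_radius, spec$pitch_per_turn,
                      spec$points_per_degree)
  sg_h <- solve_helix(spec$sg_total_length, spec$sg_total_angle,
                      spec$sg_base_radius, spec$sg_pitch_per_turn,
                      spec$points_per_degree)

  bm_s <- arc_length(bm_h$points)
  L <- bm_s[length(bm_s)]
  bm_freq <- greenwood_forward((L - bm_s) / L, spec$greenwood)

  # dendrites at equally spaced BM angles over the full span
  th <- seq(spec$bm_total_angle / spec$dendrite_count, spec$bm_total_angle,
            length.out = spec$dendrite_count)
  sg_th <- ifelse(
    th <= spec$rotation_onset_deg, th,
    spec$rotation_onset_deg +
      (th - spec$rotation_onset_deg) *
      (spec$sg_total_angle - spec$rotation_onset_deg) /
      (spec$bm_total_angle - spec$rotation_onset_deg))
  bm_idx <- vapply(th, function(a) which.min(abs(bm_h$angles - a)),
                   integer(1))
  sg_idx <- vapply(sg_th, function(a) which.min(abs(sg_h$angles - a)),
                   integer(1))
  sg_s <- arc_length(sg_h$points)

  dendrites <- lapply(seq_along(th), function(i) {
    a <- bm_h$points[bm_idx[i], ]
    b <- sg_h$points[sg_idx[i], ]
    t <- seq(0, 1, length.out = 5)
    seg <- cbind(a[1] + t * (b[1] - a[1]),
                 a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    seg[1, ] <- a   # endpoints exactly on their centerlines
    seg[5, ] <- b
    dendrite_trace(seg,
                   bm_attach = bm_s[bm_idx[i]],
                   sg_attach = sg_s[sg_idx[i]])
  })

  bm_pts <- bm_h$points
  sg_pts <- sg_h$points
  if (spec$noise_sd > 0) {
    jitter3 <- function(m)
      m + matrix(stats::rnorm(length(m), sd = spec$noise_sd), nrow = nrow(m))
    bm_pts <- jitter3(bm_pts)
    sg_pts <- jitter3(sg_pts)
    dendrites <- lapply(dendrites, function(d) {
      d$points <- jitter3(d$points)
      d
    })
  }

  structure(list(
    bm = centerline3d(bm_pts, label = "BM"),
    sg = centerline3d(sg_pts, label = "SG"),
    dendrites = dendrites,
    rw_center = bm_pts[1, ],
    truth = list(
      axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
      bm_angles = bm_h$angles, sg_angles = sg_h$angles,
      bm_freq = bm_freq,
      dendrite_bm_angle = th, dendrite_sg_angle = sg_th,
      bm_radius_decay = bm_h$decay, sg_radius_decay = sg_h$decay
    ),
    spec = spec
  ), class = "cochlea_geometry")
}

#' @export
print.cochlea_geometry <- function(x, ...) {
  cat(sprintf(
    "<cochlea_geometry> BM %.2f mm (%d pts), SG %.2f mm (%d pts), %d dendrites\n",
    total_length(x$bm), nrow(x$bm$points),
    total_length(x$sg), nrow(x$sg$points), length(x$dendrites)))
  invisible(x)
}

# ---- internal: conical helix with solved radius decay ---------------------

helix_points <- function(theta_deg, base_radius, decay_per_rad,
                         pitch_per_turn) {
  th <- theta_deg * pi / 180
  r <- base_radius * exp(-decay_per_rad * th)
  cbind(r * cos(th), r * sin(th), pitch_per_turn * theta_deg / 360)
}

helix_length <- function(total_angle, base_radius, decay_per_rad,
                         pitch_per_turn, points_per_degree) {
  th <- seq(0, total_angle, by = 1 / points_per_degree)
  pts <- helix_points(th, base_radius, decay_per_rad, pitch_per_turn)
  s <- arc_length(pts)
  s[length(s)]
}

solve_helix <- function(target_length, total_angle, base_radius,
                        pitch_per_turn, points_per_degree) {
  len <- function(c) helix_length(total_angle, base_radius, c,
                                  pitch_per_turn, points_per_degree)
  lo <- 0; hi <- 5
  if (len(lo) < target_length || len(hi) > target_length)
    stop(sprintf(
      "cannot reach length %.2f mm over %g degrees with base radius %.2f mm",
      target_length, total_angle, base_radius), call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (len(mid) > target_length) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  decay <- (lo + hi) / 2
  th <- seq(0, total_angle, by = 1 / points_per_degree)
  list(points = helix_points(th, base_radius, decay, pitch_per_turn),
       angles = th, decay = decay)
}
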