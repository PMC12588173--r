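#' Fit the mid-modiolar axis of a coiled centerline
#'
#' Estimates the central rotation axis (mid-modiolar axis) of a helically
#' coiled centerline, together with the zero-angle reference ray through the
#' round-window center. The axis is initialized from the turning direction of
#' the polyline (mean cross product of successive chords) and refined by
#' minimizing the residual sum of squares of log point-to-axis radial
#' distance about a low-order polynomial trend: the polynomial absorbs the
#' smooth base-to-apex radial taper of the cochlear spiral, so the objective
#' penalizes only the once-per-turn radial ripple that a mis-aligned axis
#' induces (coaxiality rather than circularity).
#'
#' @param bm a [centerline3d()] spanning at least a full turn about its axis.
#' @param rw_center 3D coordinate (mm) of the round-window center landmark;
#'   defines the 0-degree reference ray.
#' @param handedness `+1` or `-1`: sign of increasing angle toward the apex
#'   (left vs right ear). Default `+1`.
#' @return An object of class `modiolar_frame`: list with `axis_point` (3D
#'   point on the axis), `axis_dir` (unit vector), `zero_ray` (unit vector,
#'   orthogonal to `axis_dir`, pointing from the axis toward `rw_center`),
#'   `handedness`, and `objective` (final refinement objective value).
#' @examples
#' spec <- cochlea_spec()
#' geom <- generate_cochlea(spec)
#' frame <- fit_modiolar_axis(geom$bm, geom$rw_center)
#' @seealso [angular_depth()]
#' @export
fit_modiolar_axis <- function(bm, rw_center, handedness = 1) {
  stopifnot(inherits(bm, "centerline3d"))
  if (!handedness %in% c(-1, 1))
    stop("handedness must be +1 or -1", call. = FALSE)
  rw_center <- as.numeric(rw_center)
  if (length(rw_center) != 3L || !all(is.finite(rw_center)))
    stop("rw_center must be a finite 3D point", call. = FALSE)

  pts <- bm$points
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] / sv$d[1] < 1e-6)
    stop("axis not identifiable: centerline points are collinear",
         call. = FALSE)
  dir0 <- turning_direction(pts)
  # tie-break: orient along the net base-to-apex axial progress
  if (sum(dir0 * (pts[nrow(pts), ] - pts[1, ])) < 0) dir0 <- -dir0

  basis <- orthonormal_basis(dir0)
  e1 <- basis[, 1]; e2 <- basis[, 2]

  # refinement works on a thinned copy: coaxiality is oversampled at
  # sub-degree spacing and the objective cost scales with point count
  if (nrow(pts) > 800L)
    pts <- pts[unique(round(seq(1, nrow(pts), length.out = 800L))), ,
               drop = FALSE]

  # Detrend log radial distance with a low-order polynomial in sample index:
  # the polynomial absorbs the smooth base-to-apex radial taper but cannot
  # follow the once-per-turn ripple a mis-fit axis induces (its degree, one
  # per turn capped at 5, is far below the ripple's oscillation count).
  ang0 <- unwrap_about_axis(pts, ctr, dir0)
  span0 <- max(ang0) - min(ang0)
  if (span0 < 360)
    warning("centerline spans less than a full turn; axis fit may be weak")
  deg <- max(1L, min(5L, as.integer(round(span0 / 360))))
  qrX <- qr(cbind(1, stats::poly(seq_len(nrow(pts)), deg)))

  radial_objective <- function(par) {
    d <- unit(dir0 + par[1] * e1 + par[2] * e2)
    p0 <- ctr + par[3] * e1 + par[4] * e2
    r <- point_axis_distance(pts, p0, d)
    sum(qr.resid(qrX, log(pmax(r, 1e-12)))^2)
  }

  fit <- stats::optim(c(0, 0, 0, 0), radial_objective, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 200))
  fit <- stats::optim(fit$par, radial_objective, method = "BFGS",
                      control = list(reltol = 1e-8, maxit = 200))
  axis_dir <- unit(dir0 + fit$par[1] * e1 + fit$par[2] * e2)
  if (sum(axis_dir * (pts[nrow(pts), ] - ctr)) < 0) axis_dir <- -axis_dir
  axis_point <- ctr + fit$par[3] * e1 + fit$par[4] * e2

  rej <- reject_from_axis(rw_center, axis_point, axis_dir)
  if (vnorm(rej) < 1e-6)
    stop("round-window center lies on the fitted axis; zero ray undefined",
         call. = FALSE)

  structure(
    list(axis_point = axis_point, axis_dir = axis_dir,
         zero_ray = unit(rej), handedness = handedness,
         objective = fit$value),
    class = "modiolar_frame"
  )
}

#' Construct a modiolar frame from known axis and landmark
#'
#' Builds a `modiolar_frame` directly from a known axis (e.g. the ground
#' truth of a synthetic geometry) instead of fitting one.
#'
#' @param axis_point 3D point on the axis (mm).
#' @param axis_dir axis direction (normalized internally).
#' @param rw_center round-window-center landmark defining the zero ray.
#' @param handedness `+1` or `-1`.
#' @return A `modiolar_frame`; see [fit_modiolar_axis()].
#' @export
modiolar_frame <- function(axis_point, axis_dir, rw_center, handedness = 1) {
  if (!handedness %in% c(-1, 1))
    stop("handedness must be +1 or -1", call. = FALSE)
  axis_point <- as.numeric(axis_point)
  axis_dir <- unit(as.numeric(axis_dir))
  rej <- reject_from_axis(as.numeric(rw_center), axis_point, axis_dir)
  if (vnorm(rej) < 1e-6)
    stop("round-window center lies on the axis; zero ray undefined",
         call. = FALSE)
  structure(
    list(axis_point = axis_point, axis_dir = axis_dir, zero_ray = unit(rej),
         handedness = handedness, objective = NA_real_),
    class = "modiolar_frame"
  )
}

#' @export
print.modiolar_frame <- function(x, ...) {
  cat("<modiolar_frame>\n")
  cat(sprintf("  axis point: (%.3f, %.3f, %.3f) mm\n",
              x$axis_point[1], x$axis_point[2], x$axis_point[3]))
  cat(sprintf("  axis dir:   (%.4f, %.4f, %.4f)\n",
              x$axis_dir[1], x$axis_dir[2], x$axis_dir[3]))
  cat(sprintf("  handedness: %+d\n", x$handedness))
  invisible(x)
}

#' Unwrapped angular depth of a centerline about the mid-modiolar axis
#'
#' Measures, for every point of a centerline ordered base-to-apex, the
#' handedness-signed angle between the zero-angle ray (through the
#' round-window center) and the point's projection into the plane orthogonal
#' to the axis. Angles are unwrapped cumulatively (360 added at each wrap) so
#' the profile is monotone non-decreasing and may exceed 360 degrees; the
#' first point's raw angle is taken in [-180, 180). Consecutive points must
#' not jump by 180 degrees or more about the axis (resample to <= 0.5 mm
#' spacing first if in doubt).
#'
#' @param line a [centerline3d()] ordered base to apex.
#' @param frame a `modiolar_frame` from [fit_modiolar_axis()] or
#'   [modiolar_frame()].
#' @return Numeric vector of unwrapped angular depths in degrees, one per
#'   centerline point; the last value is the structure's angular length.
#' @export
angular_depth <- function(line, frame) {
  stopifnot(inherits(line, "centerline3d"), inherits(frame, "modiolar_frame"))
  pts <- line$points
  rel <- sweep(pts, 2, frame$axis_point)
  axial <- drop(rel %*% frame$axis_dir)
  rej <- rel - outer(axial, frame$axis_dir)
  rn <- sqrt(rowSums(rej * rej))
  on_axis <- which(rn < 1e-9)
  if (length(on_axis) > 0)
    stop(sprintf(
      "angular depth undefined: point(s) %s lie on the mid-modiolar axis",
      paste(on_axis, collapse = ", ")), call. = FALSE)
  y_ref <- cross3(frame$axis_dir, frame$zero_ray)
  raw <- atan2(drop(rej %*% y_ref), drop(rej %*% frame$zero_ray))
  raw <- frame$handedness * raw * 180 / pi   # in (-180, 180]
  raw[raw >= 180] <- raw[raw >= 180] - 360   # first point convention [-180,180)
  steps <- diff(raw) %% 360                  # forward increments in [0, 360)
  raw[1] + c(0, cumsum(steps))
}

# ---- internal -------------------------------------------------------------

# Direction about which the polyline turns: length-weighted mean cross
# product of successive chords. Exact for a planar circle; directionally
# stable for tapering helices, unlike the principal directions of the cloud.
turning_direction <- function(pts) {
  # coarse chords: successive fine-grained chords are dominated by tracing
  # jitter, so thin to ~72 stations before differencing
  if (nrow(pts) > 73L)
    pts <- pts[unique(round(seq(1, nrow(pts), length.out = 73L))), ,
               drop = FALSE]
  ch <- diff(pts)
  n <- nrow(ch)
  if (n < 2L)
    stop("axis not identifiable from fewer than 3 points", call. = FALSE)
  a <- ch[-n, , drop = FALSE]
  b <- ch[-1, , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  m <- colSums(cr)
  if (vnorm(m) < 1e-12)
    stop("axis not identifiable: centerline does not turn", call. = FALSE)
  unit(m)
}

orthonormal_basis <- function(d) {
  d <- unit(d)
  seed <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(seed - sum(seed * d) * d)
  cbind(e1, cross3(d, e1))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

reject_from_axis <- function(p, p0, d) {
  rel <- p - p0
  rel - sum(rel * d) * d
}

point_axis_distance <- function(pts, p0, d) {
  rel <- sweep(pts, 2, p0)
  axial <- drop(rel %*% d)
  rej <- rel - outer(axial, d)
  sqrt(rowSums(rej * rej))
}

# unwrapped rotation angle (degrees) of points about an arbitrary axis
unwrap_about_axis <- function(pts, p0, d) {
  basis <- orthonormal_basis(d)
  rel <- sweep(pts, 2, p0)
  raw <- atan2(drop(rel %*% basis[, 2]), drop(rel %*% basis[, 1])) * 180 / pi
  steps <- diff(raw) %% 360
  steps[steps > 180] <- steps[steps > 180] - 360  # allow mild local reversal
  raw[1] + c(0, cumsum(steps))
}
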