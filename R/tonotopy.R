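#' Per-point tonotopic map of a cochlear structure
#'
#' A `tonotopic_map` records, for each point along a structure's centerline,
#' the arc position from the base (`s_mm`), the proportional distance from
#' the apex (`x`), the unwrapped angular depth (`angle_deg`), and the
#' characteristic frequency (`freq_hz`).
#'
#' @param s_mm arc positions from the base (mm).
#' @param x proportional distances from the apex in `[0, 1]`.
#' @param angle_deg unwrapped angular depths (degrees).
#' @param freq_hz characteristic frequencies (Hz).
#' @param structure label, `"OC"` or `"SG"`.
#' @return A data frame of class `tonotopic_map` with the four columns above
#'   and a `structure` attribute.
#' @export
tonotopic_map <- function(s_mm, x, angle_deg, freq_hz,
                          structure = c("OC", "SG")) {
  structure_lab <- match.arg(structure)
  n <- length(s_mm)
  stopifnot(length(x) == n, length(angle_deg) == n, length(freq_hz) == n)
  if (any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("proportional position x must lie in [0, 1]", call. = FALSE)
  out <- data.frame(s_mm = as.numeric(s_mm), x = pmin(pmax(x, 0), 1),
                    angle_deg = as.numeric(angle_deg),
                    freq_hz = as.numeric(freq_hz))
  attr(out, "structure") <- structure_lab
  class(out) <- c("tonotopic_map", "data.frame")
  out
}

#' @export
print.tonotopic_map <- function(x, ...) {
  cat(sprintf("<tonotopic_map> %s: %d points, %.0f-%.0f Hz, 0-%.0f deg\n",
              attr(x, "structure"), nrow(x),
              min(x$freq_hz), max(x$freq_hz), max(x$angle_deg)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Plot a tonotopic map
#'
#' Frequency (log scale) against angular depth or curvilinear length.
#'
#' @param x a [tonotopic_map()].
#' @param axis `"angle"` or `"length"` for the abscissa.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tonotopic_map <- function(x, axis = c("angle", "length"), ...) {
  axis <- match.arg(axis)
  p <- if (axis == "angle") x$angle_deg else x$s_mm
  xlab <- if (axis == "angle") "angular depth (degrees)" else
    "curvilinear length (mm)"
  graphics::plot(p, x$freq_hz, log = "y", type = "l", xlab = xlab,
                 ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Map organ-of-Corti positions to Greenwood frequencies
#'
#' Builds the OC tonotopic map of a basilar-membrane centerline: each point's
#' proportional distance from the apex is `x = (L - s) / L` (total length
#' `L`, arc position `s` from the base) and its frequency is
#' [greenwood_forward()] at that `x`. The map is strictly decreasing in `s`.
#'
#' @param bm a [centerline3d()] ordered base to apex.
#' @param angles unwrapped angular depths from [angular_depth()], aligned
#'   with `bm`.
#' @param params a [greenwood_params()].
#' @return A [tonotopic_map()] with structure `"OC"`.
#' @export
map_oc_frequencies <- function(bm, angles, params = greenwood_params()) {
  stopifnot(inherits(bm, "centerline3d"))
  s <- bm$cum_length
  if (length(angles) != length(s))
    stop("angles must align with the centerline points", call. = FALSE)
  L <- s[length(s)]
  x <- (L - s) / L
  tonotopic_map(s, x, angles, greenwood_forward(x, params), structure = "OC")
}

#' Peripheral dendrite trace linking OC and SG positions
#'
#' @param points 3D polyline (mm) of the traced dendrite, ordered from its
#'   basilar-membrane end to its spiral-ganglion end.
#' @param bm_attach arc position (mm from base) of the attachment on the BM
#'   centerline.
#' @param sg_attach arc position (mm from base) of the attachment on the SG
#'   centerline.
#' @return An object of class `dendrite_trace`.
#' @export
dendrite_trace <- function(points, bm_attach, sg_attach) {
  points <- as_point_matrix(points)
  if (nrow(points) < 2L)
    stop("a dendrite trace needs at least 2 points", call. = FALSE)
  stopifnot(is.numeric(bm_attach), length(bm_attach) == 1L,
            is.numeric(sg_attach), length(sg_attach) == 1L)
  structure(list(points = points, bm_attach = bm_attach,
                 sg_attach = sg_attach),
            class = "dendrite_trace")
}

#' Transfer OC frequencies to the spiral ganglion along dendrites
#'
#' Each traced peripheral dendrite carries the OC frequency at its
#' basilar-membrane attachment (linear interpolation of the OC map in
#' log-frequency at the attachment arc position) to its spiral-ganglion
#' attachment. The SG record takes the position and angular depth of the
#' nearest SG centerline point. Records are sorted by SG arc position;
#' dendrites attaching at an identical SG position are averaged in
#' log-frequency (geometric mean, i.e. linear on the semitone scale).
#'
#' @param oc_map OC [tonotopic_map()] from [map_oc_frequencies()].
#' @param dendrites list of [dendrite_trace()] objects (>= 2).
#' @param sg SG [centerline3d()].
#' @param sg_angles angular depths aligned with `sg` (see [angular_depth()]).
#' @param bm optional BM [centerline3d()]; when given, dendrite BM endpoints
#'   are validated against it.
#' @param tol attachment tolerance in mm: each dendrite endpoint must lie
#'   within `tol` of its attached centerline. Default 0.2.
#' @return A [tonotopic_map()] with structure `"SG"`, one record per
#'   dendrite (fewer if coincident attachments were merged).
#' @export
transfer_to_sg <- function(oc_map, dendrites, sg, sg_angles, bm = NULL,
                           tol = 0.2) {
  stopifnot(inherits(oc_map, "tonotopic_map"), inherits(sg, "centerline3d"))
  if (length(sg_angles) != nrow(sg$points))
    stop("sg_angles must align with the SG centerline", call. = FALSE)
  if (!is.list(dendrites) || length(dendrites) < 2L)
    stop("transfer_to_sg needs at least 2 dendrite traces", call. = FALSE)
  lapply(dendrites, function(d)
    if (!inherits(d, "dendrite_trace"))
      stop("dendrites must be dendrite_trace objects", call. = FALSE))

  for (i in seq_along(dendrites)) {
    d <- dendrites[[i]]
    sg_end <- d$points[nrow(d$points), ]
    if (min_point_distance(sg_end, sg$points) > tol)
      stop(sprintf(
        "dendrite %d: SG endpoint is %.3f mm from the SG centerline (tol %.3f)",
        i, min_point_distance(sg_end, sg$points), tol), call. = FALSE)
    if (!is.null(bm)) {
      bm_end <- d$points[1L, ]
      if (min_point_distance(bm_end, bm$points) > tol)
        stop(sprintf(
          "dendrite %d: BM endpoint is %.3f mm from the BM centerline (tol %.3f)",
          i, min_point_distance(bm_end, bm$points), tol), call. = FALSE)
    }
  }

  s_bm <- vapply(dendrites, function(d) d$bm_attach, numeric(1))
  if (any(s_bm < min(oc_map$s_mm) - tol) || any(s_bm > max(oc_map$s_mm) + tol))
    stop("dendrite BM attachment outside the OC map's arc range",
         call. = FALSE)
  lf <- stats::approx(oc_map$s_mm, log(oc_map$freq_hz),
                      xout = pmin(pmax(s_bm, min(oc_map$s_mm)),
                                  max(oc_map$s_mm)))$y
  idx <- vapply(dendrites, function(d)
    which.min(abs(sg$cum_length - d$sg_attach)), integer(1))
  s_sg <- sg$cum_length[idx]
  ang <- sg_angles[idx]

  # merge coincident SG attachments: geometric-mean frequency
  key <- match(s_sg, s_sg)
  agg_lf <- tapply(lf, key, mean)
  keep <- as.integer(names(agg_lf))
  ord <- order(s_sg[keep])
  keep <- keep[ord]
  L <- total_length(sg)
  tonotopic_map(s_sg[keep], (L - s_sg[keep]) / L, ang[keep],
                exp(agg_lf[as.character(keep)]), structure = "SG")
}

#' Semitone difference between two frequencies
#'
#' Absolute musical interval `|12 log2(f1/f2)|` between two frequencies;
#' 12 semitones per octave (frequency ratio 2).
#'
#' @param f1,f2 frequencies in Hz (vectorized, > 0).
#' @return Absolute difference in semitones.
#' @examples
#' semitone_difference(519, 463) # ~2.0
#' @export
semitone_difference <- function(f1, f2) {
  if (any(!is.finite(f1)) || any(!is.finite(f2)) || any(f1 <= 0) ||
      any(f2 <= 0))
    stop("frequencies must be positive and finite", call. = FALSE)
  abs(12 * log2(f1 / f2))
}

#' Tonotopic rate of change in semitones per unit
#'
#' Estimates the local rate of change of the tonotopic map,
#' `12 |d log2 f / d p|`, against curvilinear length (semitones/mm) or
#' angular depth (semitones/degree). The log2-frequency series is smoothed
#' with a moving average over `smoothing_window` axis units, then
#' differentiated by central finite differences (one-sided at the ends).
#'
#' @param map a [tonotopic_map()], strictly monotone in the chosen axis,
#'   with at least 3 points.
#' @param axis `"angle"` (degrees) or `"length"` (mm).
#' @param smoothing_window moving-average window in axis units; default 30
#'   degrees for `"angle"`, 1 mm for `"length"`. Use 0 for no smoothing.
#' @return A data frame of class `rate_profile` with columns `position` and
#'   `rate`, and a `unit` attribute (`"semitones/degree"` or
#'   `"semitones/mm"`).
#' @export
rate_of_change <- function(map, axis = c("angle", "length"),
                           smoothing_window = NULL) {
  stopifnot(inherits(map, "tonotopic_map"))
  axis <- match.arg(axis)
  p <- if (axis == "angle") map$angle_deg else map$s_mm
  if (nrow(map) < 3L)
    stop("rate_of_change needs at least 3 points", call. = FALSE)
  dp <- diff(p)
  if (!(all(dp > 0) || all(dp < 0)))
    stop("map is not strictly monotone along the chosen axis", call. = FALSE)
  if (is.null(smoothing_window))
    smoothing_window <- if (axis == "angle") 30 else 1
  lf <- log2(map$freq_hz)
  pe <- p
  if (smoothing_window > 0) {
    half <- smoothing_window / 2 + 1e-9 * max(abs(p))
    sm <- vapply(seq_along(p), function(i) {
      w <- abs(p - p[i]) <= half
      c(mean(lf[w]), mean(p[w]))
    }, numeric(2))
    lf <- sm[1, ]
    # near the ends the window is one-sided; differencing against the
    # window's centroid position keeps the estimate unbiased there
    pe <- sm[2, ]
  }
  n <- length(p)
  rate <- numeric(n)
  rate[1] <- (lf[2] - lf[1]) / (pe[2] - pe[1])
  rate[n] <- (lf[n] - lf[n - 1]) / (pe[n] - pe[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- (lf[i + 1] - lf[i - 1]) / (pe[i + 1] - pe[i - 1])
  }
  out <- data.frame(position = p, rate = 12 * abs(rate))
  attr(out, "unit") <- if (axis == "angle") "semitones/degree" else
    "semitones/mm"
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> %d points, %s (mean %.3g)\n",
              nrow(x), attr(x, "unit"), mean(x$rate)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Octave-band boundaries of a tonotopic map
#'
#' Finds the boundaries `ref_hz * 2^n` (integer `n`) lying within the map's
#' frequency range and interpolates their curvilinear and angular positions
#' along the structure (monotone interpolation in log2-frequency).
#'
#' @param map a [tonotopic_map()], strictly monotone in frequency.
#' @param ref_hz reference frequency in Hz, within the map's range.
#' @return A data frame with columns `freq_hz`, `s_mm`, `angle_deg`, ordered
#'   by increasing frequency.
#' @export
octave_bands <- function(map, ref_hz) {
  stopifnot(inherits(map, "tonotopic_map"))
  f <- map$freq_hz
  df <- diff(f)
  if (!(all(df > 0) || all(df < 0)))
    stop("map frequencies are not strictly monotone", call. = FALSE)
  lo <- min(f); hi <- max(f)
  if (ref_hz < lo * (1 - 1e-9) || ref_hz > hi * (1 + 1e-9))
    stop(sprintf("ref_hz %.4g outside map frequency range [%.4g, %.4g]",
                 ref_hz, lo, hi), call. = FALSE)
  n_lo <- ceiling(log2(lo / ref_hz) - 1e-9)
  n_hi <- floor(log2(hi / ref_hz) + 1e-9)
  bounds <- ref_hz * 2^(n_lo:n_hi)
  lf <- log2(f)
  ord <- order(lf)
  s <- stats::approx(lf[ord], map$s_mm[ord], xout = log2(bounds))$y
  a <- stats::approx(lf[ord], map$angle_deg[ord], xout = log2(bounds))$y
  data.frame(freq_hz = bounds, s_mm = s, angle_deg = a)
}

# ---- internal -------------------------------------------------------------

min_point_distance <- function(p, pts) {
  rel <- sweep(pts, 2, p)
  sqrt(min(rowSums(rel * rel)))
}
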