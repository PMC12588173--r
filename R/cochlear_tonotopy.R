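#' Fit a full cochlear tonotopic analysis
#'
#' Runs the complete mapping pipeline on traced 3D centerlines: fits (or
#' accepts) the mid-modiolar frame, measures unwrapped angular depths of the
#' basilar-membrane (BM) and spiral-ganglion (SG) centerlines, maps the organ
#' of Corti (OC) to characteristic frequency with the Greenwood function, and
#' transfers OC frequencies to the SG along traced peripheral dendrites.
#'
#' @param bm BM [centerline3d()] ordered base to apex.
#' @param sg SG [centerline3d()] ordered base to apex.
#' @param dendrites list of [dendrite_trace()] objects (>= 2).
#' @param rw_center round-window-center landmark (3D point, mm); defines the
#'   0-degree ray. Ignored when `frame` is supplied.
#' @param handedness `+1` (left ear, default) or `-1`.
#' @param params a [greenwood_params()].
#' @param frame optional precomputed `modiolar_frame`; when `NULL` the axis
#'   is fitted from the BM centerline with [fit_modiolar_axis()].
#' @param dendrite_tol attachment tolerance (mm) for dendrite endpoints.
#' @return An object of class `cochlear_tonotopy`: list with `frame`,
#'   `oc_map`, `sg_map` ([tonotopic_map()]), `params`, `bm_length_mm`,
#'   `sg_length_mm`, `bm_angle_deg`, `sg_angle_deg`. Supports `print()`,
#'   `summary()`, `plot()`, and `coef()` (the Greenwood parameters).
#' @examples
#' geom <- generate_cochlea(cochlea_spec())
#' fit <- cochlear_tonotopy(geom$bm, geom$sg, geom$dendrites, geom$rw_center)
#' summary(fit)
#' @export
cochlear_tonotopy <- function(bm, sg, dendrites, rw_center, handedness = 1,
                              params = greenwood_params(), frame = NULL,
                              dendrite_tol = 0.2) {
  stopifnot(inherits(bm, "centerline3d"), inherits(sg, "centerline3d"))
  if (is.null(frame))
    frame <- fit_modiolar_axis(bm, rw_center, handedness = handedness)
  stopifnot(inherits(frame, "modiolar_frame"))
  bm_angles <- angular_depth(bm, frame)
  sg_angles <- angular_depth(sg, frame)
  oc_map <- map_oc_frequencies(bm, bm_angles, params)
  sg_map <- transfer_to_sg(oc_map, dendrites, sg, sg_angles, bm = bm,
                           tol = dendrite_tol)
  structure(list(
    frame = frame, oc_map = oc_map, sg_map = sg_map, params = params,
    bm_length_mm = total_length(bm), sg_length_mm = total_length(sg),
    bm_angle_deg = max(bm_angles), sg_angle_deg = max(sg_angles)
  ), class = "cochlear_tonotopy")
}

#' @export
print.cochlear_tonotopy <- function(x, ...) {
  cat("Cochlear tonotopic analysis\n")
  cat(sprintf("  BM: %.2f mm over %.0f degrees (%d OC map points)\n",
              x$bm_length_mm, x$bm_angle_deg, nrow(x$oc_map)))
  cat(sprintf("  SG: %.2f mm over %.0f degrees (%d dendrite-derived points)\n",
              x$sg_length_mm, x$sg_angle_deg, nrow(x$sg_map)))
  cat(sprintf("  OC frequency span: %.0f-%.0f Hz\n",
              min(x$oc_map$freq_hz), max(x$oc_map$freq_hz)))
  invisible(x)
}

#' @export
summary.cochlear_tonotopy <- function(object, step = 90, ...) {
  out <- list(
    lengths = c(bm_mm = object$bm_length_mm, sg_mm = object$sg_length_mm),
    angles = c(bm_deg = object$bm_angle_deg, sg_deg = object$sg_angle_deg),
    table = tonotopy_table(object$oc_map, object$sg_map, step = step),
    params = object$params
  )
  class(out) <- "summary.cochlear_tonotopy"
  out
}

#' @export
print.summary.cochlear_tonotopy <- function(x, ...) {
  cat(sprintf("BM %.2f mm / %.0f deg;  SG %.2f mm / %.0f deg\n",
              x$lengths["bm_mm"], x$angles["bm_deg"],
              x$lengths["sg_mm"], x$angles["sg_deg"]))
  print(x$params)
  cat("\nOC/SG frequencies at angular increments:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cochlear_tonotopy <- function(object, ...) {
  c(A = object$params$A, a = object$params$a, k = object$params$k)
}

#' Plot the OC and SG angle-frequency relationship
#'
#' Log-frequency against unwrapped angular depth for both structures, the
#' standard view in which basal alignment and apical SG compression of the
#' tonotopic maps are read off.
#'
#' @param x a [cochlear_tonotopy()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cochlear_tonotopy <- function(x, ...) {
  graphics::plot(x$oc_map$angle_deg, x$oc_map$freq_hz, log = "y", type = "l",
                 col = "darkgreen", xlab = "angular depth (degrees)",
                 ylab = "frequency (Hz)", ...)
  graphics::lines(x$sg_map$angle_deg, x$sg_map$freq_hz, col = "goldenrod")
  graphics::points(x$sg_map$angle_deg, x$sg_map$freq_hz, col = "goldenrod",
                   pch = 20, cex = 0.5)
  graphics::legend("topright", legend = c("OC", "SG"), bty = "n",
                   col = c("darkgreen", "goldenrod"), lty = 1)
  invisible(x)
}
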