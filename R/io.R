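#' Labelled 3D point set
#'
#' A named collection of labelled 3D points (mm, RAS convention), the
#' interchange carrier between traced landmark files and centerlines.
#'
#' @param points data frame with columns `label`, `x`, `y`, `z` (mm).
#' @param name set name.
#' @param source provenance: a file path or `"synthetic"`.
#' @return A data frame of class `labeled_point_set` with attributes `name`
#'   and `source`.
#' @export
labeled_point_set <- function(points, name = "points", source = "synthetic") {
  points <- as.data.frame(points)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(points)))
    stop("point set needs columns label, x, y, z", call. = FALSE)
  points <- points[, need]
  points$label <- as.character(points$label)
  for (v in c("x", "y", "z")) points[[v]] <- as.numeric(points[[v]])
  if (anyDuplicated(points$label))
    stop("point labels must be unique within a set", call. = FALSE)
  if (!all(is.finite(as.matrix(points[, c("x", "y", "z")]))))
    stop("coordinates must be finite", call. = FALSE)
  attr(points, "name") <- name
  attr(points, "source") <- source
  class(points) <- c("labeled_point_set", "data.frame")
  points
}

#' Coordinates of a labelled point set as a matrix
#'
#' @param ps a [labeled_point_set()].
#' @return n x 3 numeric matrix (mm).
#' @export
point_matrix <- function(ps) {
  stopifnot(inherits(ps, "labeled_point_set"))
  as.matrix(ps[, c("x", "y", "z")])
}

#' Read a 3D Slicer markups fiducial file
#'
#' Parses the `.mrk.json` dialect (markups, controlPoints, position
#' triplets), honouring the `coordinateSystem` field. Coordinates are
#' returned in RAS: LPS files have x and y negated. Point order and labels
#' are preserved.
#'
#' @param path path to a `.mrk.json` file.
#' @return A [labeled_point_set()].
#' @export
read_markups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed markups JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$markups) || length(doc$markups) < 1L)
    stop("markups file ", path, " has no 'markups' entry", call. = FALSE)
  mk <- doc$markups[[1]]
  cs <- mk$coordinateSystem
  if (is.null(cs)) cs <- "LPS"  # Slicer's default interchange
  if (!cs %in% c("RAS", "LPS"))
    stop("unsupported coordinateSystem '", cs, "' in ", path, call. = FALSE)
  cps <- mk$controlPoints
  if (is.null(cps) || length(cps) == 0L)
    stop("markups file ", path, " has no controlPoints", call. = FALSE)
  rows <- lapply(seq_along(cps), function(i) {
    cp <- cps[[i]]
    pos <- cp$position
    if (is.null(pos) || length(pos) != 3L)
      stop("control point ", i, " in ", path,
           " lacks a 3-element position", call. = FALSE)
    lab <- cp$label
    if (is.null(lab)) lab <- sprintf("P%d", i)
    data.frame(label = as.character(lab), x = as.numeric(pos[[1]]),
               y = as.numeric(pos[[2]]), z = as.numeric(pos[[3]]))
  })
  pts <- do.call(rbind, rows)
  if (cs == "LPS") {
    pts$x <- -pts$x
    pts$y <- -pts$y
  }
  nm <- if (!is.null(mk$name)) mk$name else "points"
  labeled_point_set(pts, name = nm, source = path)
}

#' Write a 3D Slicer markups fiducial file
#'
#' Writes a `.mrk.json` fiducial file. Internal coordinates are RAS; with
#' `coordinate_system = "LPS"` the x and y coordinates are negated on output.
#'
#' @param ps a [labeled_point_set()].
#' @param path output path.
#' @param coordinate_system `"RAS"` (default) or `"LPS"`.
#' @return Invisibly, `path`.
#' @export
write_markups <- function(ps, path, coordinate_system = c("RAS", "LPS")) {
  stopifnot(inherits(ps, "labeled_point_set"))
  coordinate_system <- match.arg(coordinate_system)
  sgn <- if (coordinate_system == "LPS") -1 else 1
  cps <- lapply(seq_len(nrow(ps)), function(i) list(
    id = as.character(i),
    label = ps$label[i],
    position = c(sgn * ps$x[i], sgn * ps$y[i], ps$z[i])
  ))
  doc <- list(
    `@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json",
    markups = list(list(
      type = "Fiducial",
      name = attr(ps, "name"),
      coordinateSystem = coordinate_system,
      controlPoints = cps
    ))
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a labelled point CSV
#'
#' Expects a header `label,x,y,z` with coordinates in mm (RAS).
#'
#' @param path path to the CSV file.
#' @return A [labeled_point_set()].
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("point CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  labeled_point_set(df, name = basename(path), source = path)
}

#' Write a labelled point CSV
#'
#' @param ps a [labeled_point_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_points_csv <- function(ps, path) {
  stopifnot(inherits(ps, "labeled_point_set"))
  df <- as.data.frame(ps)
  df$x <- sprintf("%.9f", df$x)
  df$y <- sprintf("%.9f", df$y)
  df$z <- sprintf("%.9f", df$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summary table of OC and SG frequencies at fixed angular increments
#'
#' Interpolates both tonotopic maps at regular angular-depth increments and
#' tabulates the OC frequency, the SG frequency, and their absolute semitone
#' difference. Beyond the SG's angular extent the SG and semitone cells are
#' `NA`. Frequencies are interpolated linearly in log-frequency.
#'
#' @param oc_map OC [tonotopic_map()].
#' @param sg_map SG [tonotopic_map()] (optional; `NULL` gives OC only).
#' @param step angular increment in degrees (default 90).
#' @return Data frame with columns `angle_deg`, `oc_hz` (integer), `sg_hz`
#'   (integer or `NA`), `semitone_diff` (one decimal or `NA`).
#' @export
tonotopy_table <- function(oc_map, sg_map = NULL, step = 90) {
  stopifnot(inherits(oc_map, "tonotopic_map"))
  grid <- seq(0, max(oc_map$angle_deg), by = step)
  interp_hz <- function(map, ang) {
    within <- ang >= min(map$angle_deg) - 1e-9 &
      ang <= max(map$angle_deg) + 1e-9
    out <- rep(NA_real_, length(ang))
    out[within] <- exp(stats::approx(map$angle_deg, log(map$freq_hz),
                                     xout = ang[within], rule = 2)$y)
    out
  }
  oc <- interp_hz(oc_map, grid)
  sg <- if (is.null(sg_map)) rep(NA_real_, length(grid)) else
    interp_hz(sg_map, grid)
  st <- rep(NA_real_, length(grid))
  ok <- !is.na(sg)
  if (any(ok))
    st[ok] <- round_half_up(semitone_difference(oc[ok], sg[ok]), 1)
  sg_int <- rep(NA_integer_, length(grid))
  sg_int[ok] <- as.integer(round_half_up(sg[ok]))
  data.frame(angle_deg = grid,
             oc_hz = as.integer(round_half_up(oc)),
             sg_hz = sg_int,
             semitone_diff = st)
}

#' Write pipeline report tables
#'
#' Emits deterministic TSV reports for a completed tonotopic analysis:
#' `tonotopy_table.tsv` (OC/SG frequencies and absolute semitone difference
#' at 90-degree increments, `N/A` beyond the SG extent), `rate_profiles.tsv`
#' (rate of change against angle and length for each structure), and, when
#' morphometry results are supplied, `morphometry.tsv`. Frequencies are
#' printed as integer Hz, semitones to one decimal, percentages as integers.
#'
#' @param fit a [cochlear_tonotopy()] result.
#' @param dir output directory (created if needed).
#' @param morphometry optional [apical_innervation()] summary.
#' @param step angular increment for the summary table, degrees.
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(fit, dir, morphometry = NULL, step = 90) {
  stopifnot(inherits(fit, "cochlear_tonotopy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)

  tab <- tonotopy_table(fit$oc_map, fit$sg_map, step = step)
  out <- data.frame(
    angle_deg = tab$angle_deg,
    oc_hz = as.character(tab$oc_hz),
    sg_hz = ifelse(is.na(tab$sg_hz), "N/A", as.character(tab$sg_hz)),
    semitone_diff = ifelse(is.na(tab$semitone_diff), "N/A",
                           sprintf("%.1f", tab$semitone_diff))
  )
  f1 <- file.path(dir, "tonotopy_table.tsv")
  utils::write.table(out, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f1)

  rates <- do.call(rbind, lapply(c("OC", "SG"), function(st) {
    map <- if (st == "OC") fit$oc_map else fit$sg_map
    do.call(rbind, lapply(c("angle", "length"), function(ax) {
      rp <- rate_of_change(map, axis = ax)
      data.frame(structure = st, axis = ax,
                 position = sprintf("%.4f", rp$position),
                 rate = sprintf("%.6f", rp$rate))
    }))
  }))
  f2 <- file.path(dir, "rate_profiles.tsv")
  utils::write.table(rates, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f2)

  if (!is.null(morphometry)) {
    stopifnot(inherits(morphometry, "morphometry_summary"))
    m <- data.frame(
      quantity = c("neurons_scaled", "ihcs", "axons_per_ihc",
                   "cylinder_capacity", "target_length_mm"),
      value = c(sprintf("%d", morphometry$neurons),
                sprintf("%d", morphometry$ihcs),
                sprintf("%.1f", morphometry$axons_per_ihc),
                sprintf("%d", morphometry$cylinder_capacity),
                sprintf("%.2f", morphometry$target_length))
    )
    f3 <- file.path(dir, "morphometry.tsv")
    utils::write.table(m, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f3)
  }
  invisible(files)
}
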