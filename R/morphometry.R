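#' Innervation-density morphometry parameters
#'
#' Dimensions and counts used by the apical innervation-density estimates:
#' the spiral-ganglion soma packed into a cylindrical ganglion volume, the
#' inner-hair-cell (IHC) linear density along the organ of Corti, and a
#' reference count of cross-sectioned myelinated peripheral axons.
#'
#' Defaults describe the apical human spiral ganglion: type I soma diameter
#' 22 um (0.022 mm) packed in a 1.51 mm long, 200 um diameter cylinder;
#' around 100 IHCs per mm apically; 3694 myelinated peripheral axons
#' supplying the 4.35 mm apical turn.
#'
#' @param cell_diameter soma diameter in mm.
#' @param cylinder_length ganglion cylinder length in mm.
#' @param cylinder_diameter ganglion cylinder diameter in mm.
#' @param packing_fraction fraction of the cylinder volume occupied by soma,
#'   in (0, 1]; 1 = pure volume ratio (no packing correction).
#' @param ihc_density IHCs per mm along the organ of Corti.
#' @param axon_count reference axon count (integer >= 0).
#' @param axon_ref_length organ-of-Corti length (mm) the reference axon count
#'   corresponds to.
#' @return An object of class `morphometry_params`.
#' @export
morphometry_params <- function(cell_diameter = 0.022,
                               cylinder_length = 1.51,
                               cylinder_diameter = 0.2,
                               packing_fraction = 1,
                               ihc_density = 100,
                               axon_count = 3694,
                               axon_ref_length = 4.35) {
  stopifnot(cell_diameter > 0, cylinder_length > 0, cylinder_diameter > 0,
            packing_fraction > 0, packing_fraction <= 1,
            ihc_density > 0, axon_count >= 0, axon_ref_length > 0)
  structure(list(cell_diameter = cell_diameter,
                 cylinder_length = cylinder_length,
                 cylinder_diameter = cylinder_diameter,
                 packing_fraction = packing_fraction,
                 ihc_density = ihc_density,
                 axon_count = as.integer(round(axon_count)),
                 axon_ref_length = axon_ref_length),
            class = "morphometry_params")
}

#' Cylinder-packing estimate of spiral-ganglion neuron count
#'
#' Number of spherical soma of diameter `cell_diameter` fitting (by volume)
#' into the ganglion cylinder:
#' `floor(packing_fraction * V_cylinder / V_sphere)`. Flooring reflects that
#' the count cannot exceed the volume capacity.
#'
#' @param p a [morphometry_params()].
#' @return Integer neuron count.
#' @examples
#' estimate_neurons_cylinder(morphometry_params()) # 8509
#' @export
estimate_neurons_cylinder <- function(p) {
  stopifnot(inherits(p, "morphometry_params"))
  if (p$cell_diameter > p$cylinder_diameter)
    stop("cell diameter exceeds cylinder diameter", call. = FALSE)
  v_cyl <- pi * (p$cylinder_diameter / 2)^2 * p$cylinder_length
  v_cell <- (4 / 3) * pi * (p$cell_diameter / 2)^3
  as.integer(floor(p$packing_fraction * v_cyl / v_cell))
}

#' Scale an axon count to another organ-of-Corti length
#'
#' Linear density scaling: `round(n * target_length / ref_length)` (half up),
#' assuming the axon density per mm persists over the target extent.
#'
#' @param n axon count observed over `ref_length`.
#' @param ref_length length (mm) the count was observed over.
#' @param target_length length (mm) to extrapolate to.
#' @return Integer count.
#' @examples
#' scale_axon_count(3694, 4.35, 9.6) # 8152
#' @export
scale_axon_count <- function(n, ref_length, target_length) {
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("n must be a non-negative count", call. = FALSE)
  if (ref_length <= 0 || target_length <= 0)
    stop("lengths must be positive", call. = FALSE)
  as.integer(round_half_up(n * target_length / ref_length))
}

#' Inner-hair-cell count over a length of organ of Corti
#'
#' @param density_per_mm IHCs per mm (> 0).
#' @param length_mm organ-of-Corti length in mm (> 0).
#' @return Integer count, `round(density * length)` (half up).
#' @examples
#' estimate_ihc_count(100, 9.6) # 960
#' @export
estimate_ihc_count <- function(density_per_mm, length_mm) {
  if (density_per_mm <= 0 || length_mm <= 0)
    stop("density and length must be positive", call. = FALSE)
  as.integer(round_half_up(density_per_mm * length_mm))
}

#' Innervation ratio: afferent axons per inner hair cell
#'
#' @param neurons neuron (axon) count (>= 0).
#' @param ihcs inner-hair-cell count (> 0).
#' @return Ratio rounded to one decimal.
#' @examples
#' innervation_ratio(8152, 960) # 8.5
#' @export
innervation_ratio <- function(neurons, ihcs) {
  if (ihcs <= 0) stop("ihcs must be positive", call. = FALSE)
  if (neurons < 0) stop("neurons must be non-negative", call. = FALSE)
  round_half_up(neurons / ihcs, 1)
}

#' Fraction of a structure's length, as an integer percent
#'
#' @param part_length part length in mm (`0 <= part <= total`).
#' @param total_length total length in mm (> 0).
#' @return Integer percent, `100 * part / total` rounded half up.
#' @examples
#' apical_fraction(9.6, 34.10) # 28
#' @export
apical_fraction <- function(part_length, total_length) {
  if (total_length <= 0) stop("total length must be positive", call. = FALSE)
  if (part_length < 0 || part_length > total_length)
    stop("part length must lie in [0, total]", call. = FALSE)
  as.integer(round_half_up(100 * part_length / total_length))
}

#' Apical innervation-density summary
#'
#' Runs the full innervation-density arithmetic for an apical region: scales
#' the reference axon count to the region's organ-of-Corti length, counts the
#' IHCs it contains, derives the innervation ratio, and reports the
#' cylinder-packing neuron capacity alongside for comparison.
#'
#' @param p a [morphometry_params()].
#' @param target_length organ-of-Corti length of the region (mm); default
#'   9.6 (the 20-500 Hz apical region).
#' @return A list of class `morphometry_summary`: `neurons` (scaled axon
#'   count), `ihcs`, `axons_per_ihc`, `cylinder_capacity`, and the inputs.
#' @examples
#' summary <- apical_innervation(morphometry_params())
#' summary$axons_per_ihc # 8.5
#' @export
apical_innervation <- function(p = morphometry_params(), target_length = 9.6) {
  stopifnot(inherits(p, "morphometry_params"))
  neurons <- scale_axon_count(p$axon_count, p$axon_ref_length, target_length)
  ihcs <- estimate_ihc_count(p$ihc_density, target_length)
  structure(list(
    neurons = neurons,
    ihcs = ihcs,
    axons_per_ihc = innervation_ratio(neurons, ihcs),
    cylinder_capacity = estimate_neurons_cylinder(p),
    target_length = target_length,
    params = p
  ), class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("Apical innervation over %.2f mm of organ of Corti:\n",
              x$target_length))
  cat(sprintf("  neurons (axon-density scaling): %d\n", x$neurons))
  cat(sprintf("  inner hair cells:               %d\n", x$ihcs))
  cat(sprintf("  axons per IHC:                  %.1f\n", x$axons_per_ihc))
  cat(sprintf("  cylinder-packing capacity:      %d neurons\n",
              x$cylinder_capacity))
  invisible(x)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # epsilon guards against representation error in products such as
  # 110 * 4.35 = 478.49999999999994
  floor(x * m + 0.5 + 1e-9 * pmax(1, abs(x * m))) / m
}
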