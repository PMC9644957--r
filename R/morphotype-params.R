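#' Parametric skull morphotype description
#'
#' Bundles the dimensions that define one parametric longirostrine skull:
#' an elongated tapered rostrum (elliptical cross-section shrinking
#' anteriorly) fused to a box-like posterior cranium with lateral orbital
#' voids. All lengths are in mm; the mesh generated from these parameters
#' uses a consistent mm-N-MPa unit system (anteroposterior = +x with
#' anterior positive, bilateral symmetry plane y = 0, dorsal = +z).
#'
#' @param label identifier, e.g. `"robust"` or `"gracile"`.
#' @param total_skull_length total skull length, mm.
#' @param rostrum_fraction share of total length anterior to the orbit
#'   region, in (0, 1).
#' @param rostrum_base_height rostrum cross-section height at its base, mm.
#' @param rostrum_base_width rostrum cross-section width at its base, mm.
#' @param taper_exponent positive exponent controlling how fast the snout
#'   cross-section shrinks towards the tip (1 = linear taper; < 1 tapers
#'   fast near the base then runs slender).
#' @param cranium_height posterior cranium height, mm.
#' @param cranium_width posterior cranium width, mm.
#' @param orbit_diameter orbit diameter, mm; the orbit is a lateral void.
#' @param target_edge_length requested mesh edge length, mm. Must not
#'   exceed `rostrum_base_width / 3` so the snout is at least three
#'   elements thick.
#' @param tip_fraction cross-section height/width at the anterior tip as a
#'   fraction of the base dimensions (the snout tip is blunt, not a point).
#' @param tooth_row_start_fraction start of the tooth row as a fraction of
#'   total skull length from the posterior end.
#' @param preserved_fraction fraction of total skull length actually
#'   represented by the mesh; `< 1` emulates a specimen whose anterior
#'   rostrum is missing (the mesh is generated complete, then truncated
#'   with [truncate_rostrum()] by the pipeline).
#' @param random_seed integer seed for the (few) stochastic choices in mesh
#'   generation and node-set subsampling.
#'
#' @return an object of class `morphotype_params` (a validated named list).
#' @seealso [morphotype_preset()], [build_skull_mesh()]
#' @export
morphotype_params <- function(label,
                              total_skull_length,
                              rostrum_fraction,
                              rostrum_base_height,
                              rostrum_base_width,
                              taper_exponent = 1,
                              cranium_height,
                              cranium_width,
                              orbit_diameter,
                              target_edge_length,
                              tip_fraction = 0.25,
                              tooth_row_start_fraction = 0.37,
                              preserved_fraction = 1,
                              random_seed = 1L) {
  p <- list(
    label = as.character(label),
    total_skull_length = total_skull_length,
    rostrum_fraction = rostrum_fraction,
    rostrum_base_height = rostrum_base_height,
    rostrum_base_width = rostrum_base_width,
    taper_exponent = taper_exponent,
    cranium_height = cranium_height,
    cranium_width = cranium_width,
    orbit_diameter = orbit_diameter,
    target_edge_length = target_edge_length,
    tip_fraction = tip_fraction,
    tooth_row_start_fraction = tooth_row_start_fraction,
    preserved_fraction = preserved_fraction,
    random_seed = as.integer(random_seed)
  )
  class(p) <- "morphotype_params"
  validate_morphotype_params(p)
  p
}

#' Validate morphotype parameters
#'
#' Checks the geometric invariants of a [morphotype_params()] object and
#' fails with a message naming the offending parameter.
#' @param p a `morphotype_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_morphotype_params <- function(p) {
  lin <- c("total_skull_length", "rostrum_base_height", "rostrum_base_width",
           "cranium_height", "cranium_width", "orbit_diameter",
           "target_edge_length")
  for (f in lin) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("morphotype parameter '", f, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (p$rostrum_fraction <= 0 || p$rostrum_fraction >= 1) {
    stop("morphotype parameter 'rostrum_fraction' must lie in (0, 1)",
         call. = FALSE)
  }
  if (p$taper_exponent <= 0) {
    stop("morphotype parameter 'taper_exponent' must be > 0", call. = FALSE)
  }
  if (p$rostrum_base_width > p$cranium_width) {
    stop("'rostrum_base_width' must not exceed 'cranium_width'",
         call. = FALSE)
  }
  if (p$orbit_diameter >= p$cranium_height) {
    stop("'orbit_diameter' must be smaller than 'cranium_height'",
         call. = FALSE)
  }
  if (p$target_edge_length > p$rostrum_base_width / 3) {
    stop("'target_edge_length' (", p$target_edge_length,
         " mm) too coarse: must be <= rostrum_base_width/3 = ",
         signif(p$rostrum_base_width / 3, 3),
         " mm so the snout is at least three elements thick", call. = FALSE)
  }
  if (p$tip_fraction <= 0 || p$tip_fraction >= 1) {
    stop("'tip_fraction' must lie in (0, 1)", call. = FALSE)
  }
  if (p$preserved_fraction <= 0 || p$preserved_fraction > 1) {
    stop("'preserved_fraction' must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Load a shipped morphotype preset
#'
#' The package ships two presets as YAML files under
#' `inst/extdata/presets/`, one per study morphotype: `"robust"` (total
#' skull length 401 mm, of which 46% is preserved, emulating a specimen
#' with the anterior rostrum broken away) and `"gracile"` (335 mm,
#' complete, with a slenderer rostrum and larger orbit). Field-by-field
#' documentation lives in the YAML files themselves.
#'
#' @param name `"robust"`, `"gracile"`, or a path to a custom preset YAML.
#' @param target_edge_length optional override of the preset mesh edge
#'   length, mm (coarser for quick runs, finer for convergence checks).
#' @return a [morphotype_params()] object.
#' @export
#' @examples
#' p <- morphotype_preset("gracile")
#' p$total_skull_length
morphotype_preset <- function(name, target_edge_length = NULL) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "craniofea", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown morphotype preset '", name,
         "' (shipped presets: robust, gracile)", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (!is.null(target_edge_length)) y$target_edge_length <- target_edge_length
  do.call(morphotype_params, y)
}

#' @export
print.morphotype_params <- function(x, ...) {
  cat("Morphotype '", x$label, "': total length ", x$total_skull_length,
      " mm (rostrum fraction ", x$rostrum_fraction, ")\n", sep = "")
  cat("  rostrum base ", x$rostrum_base_width, " x ", x$rostrum_base_height,
      " mm, taper exponent ", x$taper_exponent, "\n", sep = "")
  cat("  cranium ", x$cranium_width, " x ", x$cranium_height,
      " mm, orbit ", x$orbit_diameter, " mm\n", sep = "")
  cat("  target edge length ", x$target_edge_length, " mm; preserved ",
      round(100 * x$preserved_fraction), "%\n", sep = "")
  invisible(x)
}
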