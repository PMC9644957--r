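# Dry-skull jaw-muscle force estimation. Seven jaw muscles (three external
# adductors mAMEpr/mAMEsu/mAMEme, two internal adductors mAMIps/mAMIpt, the
# posterior adductor mAMP and the depressor mDM), with dimensions consumed
# from a packaged fixture table of reconstructed lengths and volumes per
# specimen. Maximum force: F_max = (V / (L/3)) * P, i.e. muscle volume over
# fibre length (one third of total muscle length) times specific muscle
# stress P (default 0.3 MPa = 300 kPa). All computation at full precision;
# rounding only at presentation (round half away from zero).

MUSCLE_NAMES <- c("mAMEpr", "mAMEsu", "mAMEme", "mAMIps", "mAMIpt",
                  "mAMP", "mDM")

#' Jaw muscle description
#'
#' One of the seven jaw muscles with its attachment node-set names and
#' reconstructed dimensions.
#'
#' @param name one of `mAMEpr`, `mAMEsu`, `mAMEme`, `mAMIps`, `mAMIpt`,
#'   `mAMP`, `mDM`.
#' @param length_L origin-to-insertion length (longest line through the
#'   muscle), mm.
#' @param volume_V reconstructed muscle volume, mm^3.
#' @param origin_set,insertion_set node-set base names on the mesh
#'   (defaults follow the standard attachment topology: the four dorsal
#'   adductors share the coronoid insertion, the pterygoideus wraps the
#'   angular, the posterior adductor inserts on the external mandible
#'   surface, the depressor on the posterior surangular).
#' @param role `"adductor"` or `"depressor"`.
#' @return an object of class `jaw_muscle`.
#' @export
jaw_muscle <- function(name, length_L, volume_V,
                       origin_set = NULL, insertion_set = NULL,
                       role = NULL) {
  name <- match.arg(name, MUSCLE_NAMES)
  if (!is.numeric(length_L) || length_L <= 0) {
    stop("muscle length must be > 0", call. = FALSE)
  }
  if (!is.numeric(volume_V) || volume_V <= 0) {
    stop("muscle volume must be > 0", call. = FALSE)
  }
  ins_default <- c(mAMEpr = "coronoid", mAMEsu = "coronoid",
                   mAMEme = "coronoid", mAMIps = "coronoid",
                   mAMIpt = "angular", mAMP = "mandible_external",
                   mDM = "surangular")
  structure(list(
    name = name,
    length_L = length_L,
    volume_V = volume_V,
    origin_set = origin_set %||% paste0("origin_", name),
    insertion_set = insertion_set %||%
      paste0("insertion_", ins_default[[name]]),
    role = role %||% if (name == "mDM") "depressor" else "adductor"),
    class = "jaw_muscle")
}

#' Maximum muscle force from reconstructed dimensions
#'
#' Dry-skull force estimate: fibre length is one third of total muscle
#' length; average physiological cross-section is volume over fibre
#' length; maximum force is cross-section times specific muscle stress.
#' No intermediate rounding is applied.
#'
#' @param muscle a [jaw_muscle()] (or anything with `length_L` and
#'   `volume_V` fields).
#' @param muscle_stress_P specific muscle stress, MPa (default 0.3
#'   = 300 kPa, the standard measured value for living vertebrates).
#' @param n_nodes optional number of loaded nodes at the attachment; when
#'   given, the per-node force `F_max / n_nodes` is included.
#' @return a list of class `muscle_force`: `fiber_length` (mm),
#'   `cross_section_A` (mm^2), `F_max` (N), `muscle_stress_P` (MPa) and
#'   optionally `per_node_force` (N).
#' @export
#' @examples
#' mf <- muscle_force(jaw_muscle("mAMEpr", length_L = 72, volume_V = 2085))
#' round_half_out(mf$cross_section_A) # 87
#' round_half_out(mf$F_max)           # 26
muscle_force <- function(muscle, muscle_stress_P = 0.3, n_nodes = NULL) {
  if (!is.numeric(muscle_stress_P) || muscle_stress_P < 0) {
    stop("muscle stress must be >= 0", call. = FALSE)
  }
  if (muscle$length_L <= 0) stop("muscle length must be > 0", call. = FALSE)
  if (muscle$volume_V <= 0) stop("muscle volume must be > 0", call. = FALSE)
  fiber <- muscle$length_L / 3
  a <- muscle$volume_V / fiber
  f <- a * muscle_stress_P
  out <- list(name = muscle$name, fiber_length = fiber, cross_section_A = a,
              F_max = f, muscle_stress_P = muscle_stress_P)
  if (!is.null(n_nodes)) {
    stopifnot(n_nodes >= 1)
    out$per_node_force <- f / n_nodes
    out$n_nodes <- n_nodes
  }
  class(out) <- "muscle_force"
  out
}

#' Total muscle force over the seven-muscle set
#'
#' Sum of unrounded per-muscle maximum forces. By convention the total
#' includes the depressor (mDM), matching the printed specimen totals;
#' set `include_depressor = FALSE` for an adductor-only total.
#'
#' @param muscles list of the seven [jaw_muscle()] objects.
#' @param muscle_stress_P specific muscle stress, MPa.
#' @param include_depressor include muscles with role `"depressor"`
#'   (default `TRUE`).
#' @return total force, N (unrounded).
#' @export
total_muscle_force <- function(muscles, muscle_stress_P = 0.3,
                               include_depressor = TRUE) {
  names_have <- vapply(muscles, function(m) m$name, "")
  absent <- setdiff(MUSCLE_NAMES, names_have)
  if (length(absent)) {
    stop("missing muscle(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  keep <- if (include_depressor) {
    rep(TRUE, length(muscles))
  } else {
    vapply(muscles, function(m) m$role != "depressor", TRUE)
  }
  sum(vapply(muscles[keep], function(m) {
    muscle_force(m, muscle_stress_P)$F_max
  }, numeric(1)))
}

#' Packaged jaw-muscle dimension fixtures
#'
#' Reconstructed muscle lengths and volumes for the two study specimens
#' (robust morphotype M1409, gracile morphotype M1399), as transcribed
#' reference values shipped with the package.
#'
#' @param path optional CSV with columns `specimen`, `muscle`,
#'   `length_mm`, `volume_mm3`; default the packaged fixture.
#' @return data.frame of muscle dimensions.
#' @export
muscle_dimensions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "jaw_muscle_dimensions.csv",
                                package = "craniofea", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "muscle", "length_mm", "volume_mm3")
  if (!all(need %in% names(d))) {
    stop("muscle fixture must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d
}

#' Muscle set for one specimen
#'
#' @param specimen specimen identifier present in the fixture table.
#' @param dims a muscle dimension table from [muscle_dimensions()].
#' @return list of seven [jaw_muscle()] objects.
#' @export
specimen_muscles <- function(specimen, dims = muscle_dimensions()) {
  d <- dims[dims$specimen == specimen, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("specimen '", specimen, "' not in the muscle table", call. = FALSE)
  }
  lapply(seq_len(nrow(d)), function(i) {
    jaw_muscle(d$muscle[i], length_L = d$length_mm[i],
               volume_V = d$volume_mm3[i])
  })
}

#' Per-muscle force table for one specimen
#'
#' Reproduces the per-muscle report: length, volume, cross-sectional
#' area and maximum force, computed at full precision with a `rounded`
#' companion (integers, half away from zero) for presentation.
#'
#' @inheritParams specimen_muscles
#' @param muscle_stress_P specific muscle stress, MPa.
#' @return data.frame with columns `muscle`, `length_mm`, `volume_mm3`,
#'   `cross_section_mm2`, `force_N`, `cross_section_rounded`,
#'   `force_rounded`.
#' @export
muscle_force_table <- function(specimen, dims = muscle_dimensions(),
                               muscle_stress_P = 0.3) {
  ms <- specimen_muscles(specimen, dims)
  rows <- lapply(ms, function(m) {
    mf <- muscle_force(m, muscle_stress_P)
    data.frame(muscle = m$name, length_mm = m$length_L,
               volume_mm3 = m$volume_V,
               cross_section_mm2 = mf$cross_section_A,
               force_N = mf$F_max)
  })
  out <- do.call(rbind, rows)
  out$cross_section_rounded <- round_half_out(out$cross_section_mm2)
  out$force_rounded <- round_half_out(out$force_N)
  out
}

#' Node-count policy for muscle attachment loading
#'
#' Number of loaded nodes per attachment area. Defaults follow the published loading
#' protocol: 50 at the mAMIps origin, 30 at the mAMEpr origin, 35 at the
#' shared mAMEsu+mAMEme origin, a combined 115-node coronoid insertion
#' for the four dorsal adductors, and 50/25/40 nodes for mAMIpt, mAMP and
#' mDM at origin and insertion.
#'
#' @param overrides named list of count overrides.
#' @return named integer vector of class `node_count_policy`, keyed by
#'   attachment-area name.
#' @export
node_count_policy <- function(overrides = NULL) {
  counts <- c(origin_mAMIps = 50L, origin_mAMEpr = 30L,
              origin_mAMEsu = 35L, origin_mAMEme = 35L,
              origin_mAMIpt = 50L, origin_mAMP = 25L, origin_mDM = 40L,
              insertion_coronoid = 115L, insertion_angular = 50L,
              insertion_mandible_external = 25L, insertion_surangular = 40L)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) counts[nm] <- as.integer(overrides[[nm]])
  }
  if (any(counts <= 0)) stop("node counts must be positive", call. = FALSE)
  structure(counts, class = "node_count_policy")
}

# Loaded-node count at the origin of one muscle under a policy. The four
# dorsal adductors share the 115-node coronoid insertion; each keeps its
# own origin count.
policy_origin_count <- function(policy, muscle_name) {
  unname(policy[[paste0("origin_", muscle_name)]])
}

policy_insertion_count <- function(policy, insertion_set) {
  key <- sub("_(left|right)$", "", insertion_set)
  unname(policy[[key]])
}
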