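# Two-dimensional jaw lever mechanics: mechanical advantage A = in-lever /
# out-lever, bite force F = F_total * A, evaluated along the tooth row.
# Specimen fixtures carry the mechanical advantage at the tooth-row tip
# directly (in-lever lengths are recovered as A_tip * out_lever_tip).

#' Mechanical advantage of a lever
#'
#' @param in_lever jaw-joint to adductor-insertion distance, mm.
#' @param out_lever jaw-joint to bite-point distance, mm.
#' @return `in_lever / out_lever` (dimensionless). A warning (not an
#'   error) is raised when the ratio exceeds 1, which is implausible for
#'   a biting jaw.
#' @export
#' @examples
#' mechanical_advantage(10, 100) # 0.1
mechanical_advantage <- function(in_lever, out_lever) {
  if (!is.numeric(in_lever) || !is.numeric(out_lever) ||
      any(in_lever <= 0) || any(out_lever <= 0)) {
    stop("lever lengths must be positive", call. = FALSE)
  }
  a <- in_lever / out_lever
  if (any(a > 1)) {
    warning("mechanical advantage > 1: lever geometry implausible",
            call. = FALSE)
  }
  a
}

#' Bite force from total muscle force and mechanical advantage
#'
#' @param F_total total muscle force, N (unrounded; see
#'   [total_muscle_force()]).
#' @param A mechanical advantage at the bite position.
#' @return bite force, N, unrounded (round at presentation with
#'   [round_half_out()]).
#' @export
#' @examples
#' round_half_out(bite_force(157.97, 0.089)) # 14
bite_force <- function(F_total, A) {
  if (!is.numeric(F_total) || any(F_total < 0)) {
    stop("total muscle force must be >= 0", call. = FALSE)
  }
  if (!is.numeric(A) || any(A <= 0)) {
    stop("mechanical advantage must be > 0", call. = FALSE)
  }
  if (any(A > 1)) {
    warning("mechanical advantage > 1: lever geometry implausible",
            call. = FALSE)
  }
  F_total * A
}

#' Lever geometry for one specimen
#'
#' @param in_lever jaw-joint to adductor-insertion distance, mm.
#' @param out_lever_tip jaw-joint to the anterior tooth-row tip (total
#'   jaw length), mm.
#' @param out_lever_back jaw-joint to the posterior end of the tooth row,
#'   mm (optional; defaults to `out_lever_tip`, i.e. unknown).
#' @return an object of class `lever_geometry` with the tip mechanical
#'   advantage precomputed.
#' @export
lever_geometry <- function(in_lever, out_lever_tip,
                           out_lever_back = out_lever_tip) {
  if (in_lever <= 0 || out_lever_tip <= 0 || out_lever_back <= 0) {
    stop("lever lengths must be positive", call. = FALSE)
  }
  if (in_lever >= out_lever_back || out_lever_back > out_lever_tip) {
    stop("need 0 < in_lever < out_lever_back <= out_lever_tip",
         call. = FALSE)
  }
  structure(list(in_lever = in_lever, out_lever_tip = out_lever_tip,
                 out_lever_back = out_lever_back,
                 mechanical_advantage_A =
                   mechanical_advantage(in_lever, out_lever_tip)),
            class = "lever_geometry")
}

#' Bite-force profile along the tooth row
#'
#' Evaluates `F_total * in_lever / out_lever(position)` at each requested
#' out-lever distance. Bite force strictly increases from the tip towards
#' the jaw joint.
#'
#' @param lever a [lever_geometry()].
#' @param F_total total muscle force, N.
#' @param positions named numeric vector of out-lever distances, mm, in
#'   `(0, out_lever_tip]`.
#' @param specimen optional identifier carried into the result.
#' @return an object of class `bite_profile`: data.frame with columns
#'   `position`, `out_lever_mm`, `advantage`, `force_N`,
#'   `force_rounded`.
#' @export
bite_profile <- function(lever, F_total,
                         positions = c(tip = lever$out_lever_tip,
                                       back = lever$out_lever_back),
                         specimen = NULL) {
  if (any(positions <= 0) || any(positions > lever$out_lever_tip)) {
    stop("bite positions must lie in (0, out_lever_tip]", call. = FALSE)
  }
  adv <- lever$in_lever / positions
  f <- bite_force(F_total, adv)
  out <- data.frame(position = names(positions), out_lever_mm = positions,
                    advantage = adv, force_N = f,
                    force_rounded = round_half_out(f))
  if (!is.null(specimen)) out$specimen <- specimen
  class(out) <- c("bite_profile", class(out))
  attr(out, "F_total") <- F_total
  out
}

#' FEA bite-force estimate at a bite constraint set
#'
#' Sum of the vertical (dorsoventral, z) reaction components over the
#' nodes of a bite constraint set: the force the bitten prey item would
#' experience in the simulation. Comparable in order of magnitude with
#' the two-dimensional lever estimate from [bite_force()].
#'
#' @param field a `stress_field` from [fe_solve()].
#' @param mesh the mesh the field was computed on.
#' @param bite bite node-set name.
#' @return summed vertical reaction, N (positive = supporting the bite).
#' @export
fea_bite_force <- function(field, mesh, bite = "bite_anterior") {
  set <- mesh$node_sets[[bite]]
  if (is.null(set)) stop("mesh has no node set '", bite, "'", call. = FALSE)
  sel <- rownames(field$reactions) %in% set
  if (!any(sel)) {
    stop("bite set '", bite, "' was not constrained in this load case",
         call. = FALSE)
  }
  sum(field$reactions[sel, 3])
}

#' Packaged specimen lever fixtures
#'
#' Mechanical advantage at the tooth-row tip and total jaw length for the
#' two study specimens, as transcribed reference values.
#'
#' @param path optional CSV path; default the packaged fixture.
#' @return data.frame with columns `specimen`, `morphotype`,
#'   `mechanical_advantage_tip`, `out_lever_tip_mm`,
#'   `preserved_length_mm`.
#' @export
lever_fixtures <- function(path = NULL) {
  path <- path %||% system.file("extdata", "jaw_levers.csv",
                                package = "craniofea", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Back-solve the out-lever implied by a bite force
#'
#' Given a total muscle force, an in-lever and a bite force at some
#' position, returns the out-lever distance that position must have:
#' `out = F_total * in_lever / F_bite`. Used to recover the tooth-row
#' back position implied by reported back-of-row bite forces; the result
#' is a consistency quantity, not an anatomical measurement.
#'
#' @param F_total total muscle force, N.
#' @param in_lever in-lever length, mm.
#' @param F_bite bite force at the unknown position, N.
#' @return implied out-lever, mm.
#' @export
implied_out_lever <- function(F_total, in_lever, F_bite) {
  if (F_bite <= 0) stop("bite force must be > 0", call. = FALSE)
  F_total * in_lever / F_bite
}
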