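# Mesh-refinement convergence utility. The study-scale models are meshed
# far coarser than the half-millimetre elements a fossil-scale model would
# use; the claims the pipeline makes are about relative and regional
# stresses, so this utility re-runs a load case across a ladder of edge
# lengths and reports how the regional summaries move.

#' Refine morphotype parameters by a factor
#'
#' @param params a [morphotype_params()].
#' @param factor edge-length division factor (> 1 refines; 1.25 roughly
#'   doubles the element count).
#' @return the refined `morphotype_params`.
#' @export
refine_params <- function(params, factor = 1.25) {
  stopifnot(factor > 0)
  params$target_edge_length <- params$target_edge_length / factor
  validate_morphotype_params(params)
  params
}

#' Regional-stress convergence study
#'
#' Builds the morphotype at several refinement levels, solves the same
#' bite case on each, and tabulates the regional mean von Mises stress
#' per level together with the relative change between consecutive
#' levels.
#'
#' @param params a [morphotype_params()].
#' @param muscles list of [jaw_muscle()] objects for the loading.
#' @param bite bite node-set name, e.g. `"bite_mid"`.
#' @param levels number of refinement levels (default 2).
#' @param factor per-level edge division factor.
#' @param material an [fe_material()].
#' @param policy a [node_count_policy()].
#' @param keep_fraction optional rostrum truncation applied at each level.
#' @return data.frame with columns `level`, `edge_mm`, `elements`,
#'   `region`, `mean_vm`, `rel_change` (vs the previous level).
#' @export
convergence_study <- function(params, muscles, bite = "bite_mid",
                              levels = 2, factor = 1.25,
                              material = fe_material(),
                              policy = node_count_policy(),
                              keep_fraction = 1) {
  out <- list()
  prev <- NULL
  p <- params
  for (lev in seq_len(levels)) {
    mesh <- build_skull_mesh(p)
    if (keep_fraction < 1) mesh <- truncate_rostrum(mesh, keep_fraction)
    lc <- bite_load_case(mesh, muscles, bite, policy)
    field <- fe_solve(mesh, material, lc)
    rs <- region_summary(field, mesh)
    df <- data.frame(level = lev, edge_mm = p$target_edge_length,
                     elements = nrow(mesh$elements),
                     region = rs$region, mean_vm = rs$mean)
    if (!is.null(prev)) {
      m <- match(df$region, prev$region)
      df$rel_change <- (df$mean_vm - prev$mean_vm[m]) /
        abs(prev$mean_vm[m])
    } else {
      df$rel_change <- NA_real_
    }
    out[[lev]] <- df
    prev <- df
    p <- refine_params(p, factor)
  }
  do.call(rbind, out)
}
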