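# Two-nodes muscle loading: each loaded node at a muscle attachment
# carries F_max / n directed along the unit vector from itself towards its
# paired node on the opposing attachment, so forces act along the line of
# pull of the muscle. Loaded subsets are chosen by deterministic
# farthest-point subsampling of the attachment patch; pairing is nearest
# node of the opposing subset. By default only the origin side is loaded
# (the mandible-side insertion supplies direction only), mirroring a
# cranium-only model in which the mandible is absent; each body side
# carries the full per-muscle force.

#' Build nodal force vectors for one muscle
#'
#' @param mesh a `skull_mesh` with origin and insertion node sets for the
#'   muscle on both sides.
#' @param muscle a [jaw_muscle()].
#' @param result a [muscle_force()] result for that muscle.
#' @param policy a [node_count_policy()].
#' @param apply `"origin"` (default) loads only the origin-side nodes;
#'   `"both"` also applies the equal-and-opposite forces at the insertion
#'   subset.
#' @param sides which body sides to load (default both, i.e. bilateral).
#' @param exclude node indices that must not be loaded (typically the
#'   constrained nodes of the load case); they are removed from the
#'   attachment candidates before subset selection.
#' @return data.frame with columns `node`, `fx`, `fy`, `fz`, `muscle`,
#'   `side`; per side, the force magnitudes at each loaded attachment sum
#'   to `F_max`.
#' @export
build_force_vectors <- function(mesh, muscle, result, policy = node_count_policy(),
                                apply = c("origin", "both"),
                                sides = c("left", "right"),
                                exclude = NULL) {
  apply <- match.arg(apply)
  out <- list()
  # The loaded subsets are selected once on the right side and mirrored to
  # the left (when the mesh is bilaterally paired), so bilateral loading
  # is exactly mirror-symmetric irrespective of tie-breaking in the
  # farthest-point selection.
  mirror <- NULL
  select_side <- function(side) {
    oset_name <- paste0(muscle$origin_set, "_", side)
    iset_name <- paste0(muscle$insertion_set, "_", side)
    oset <- mesh$node_sets[[oset_name]]
    iset <- mesh$node_sets[[iset_name]]
    if (is.null(oset) || is.null(iset)) {
      stop("mesh lacks attachment set(s) for ", muscle$name, " on the ",
           side, " side (need '", oset_name, "' and '", iset_name, "')",
           call. = FALSE)
    }
    if (!is.null(exclude)) {
      oset <- setdiff(oset, exclude)
      iset <- setdiff(iset, exclude)
    }
    n_o <- policy_origin_count(policy, muscle$name)
    n_i <- policy_insertion_count(policy, muscle$insertion_set)
    if (is.null(n_o) || is.null(n_i)) {
      stop("node-count policy has no entry for ", muscle$name, call. = FALSE)
    }
    if (n_o > length(oset) || n_i > length(iset)) {
      stop("policy requests more loaded nodes than attachment '",
           oset_name, "'/'", iset_name, "' offers after excluding ",
           "constrained nodes (refine the mesh or shrink the policy)",
           call. = FALSE)
    }
    list(o = oset[farthest_point_sample(mesh$nodes[oset, , drop = FALSE], n_o)],
         i = iset[farthest_point_sample(mesh$nodes[iset, , drop = FALSE], n_i)],
         n_o = n_o, n_i = n_i)
  }
  sel_right <- NULL
  for (side in sides) {
    if (side == "right" || is.null(sel_right)) {
      sel <- select_side(if (side == "left" &&
                             is.null(mesh$node_sets[[paste0(
                               muscle$origin_set, "_right")]])) "left"
                         else "right")
      sel_right <- sel
    }
    if (side == "left") {
      if (is.null(mirror)) mirror <- node_mirror_map(mesh$nodes)
      mo <- mirror[sel_right$o]
      mi <- mirror[sel_right$i]
      sel <- if (anyNA(mo) || anyNA(mi)) select_side("left") else
        list(o = mo, i = mi, n_o = sel_right$n_o, n_i = sel_right$n_i)
    }
    o_nodes <- sel$o
    i_nodes <- sel$i
    n_o <- sel$n_o
    n_i <- sel$n_i

    # attachment patches may overlap on a coarse mesh: never pair a node
    # with itself, take the nearest *distinct* opposing node
    pair_to <- function(from, to) {
      a <- mesh$nodes[from, , drop = FALSE]
      b <- mesh$nodes[to, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
      d2[outer(from, to, "==")] <- Inf
      to[max.col(-d2, ties.method = "first")]
    }
    pair_o <- pair_to(o_nodes, i_nodes)
    dir_o <- mesh$nodes[pair_o, , drop = FALSE] -
      mesh$nodes[o_nodes, , drop = FALSE]
    len <- sqrt(rowSums(dir_o^2))
    if (any(len < 1e-9)) {
      stop("coincident origin/insertion nodes for ", muscle$name,
           call. = FALSE)
    }
    dir_o <- dir_o / len
    f_o <- result$F_max / n_o
    out[[length(out) + 1]] <- data.frame(
      node = o_nodes, fx = f_o * dir_o[, 1], fy = f_o * dir_o[, 2],
      fz = f_o * dir_o[, 3], muscle = muscle$name, side = side)

    if (apply == "both") {
      pair_i <- pair_to(i_nodes, o_nodes)
      dir_i <- mesh$nodes[pair_i, , drop = FALSE] -
        mesh$nodes[i_nodes, , drop = FALSE]
      dir_i <- dir_i / sqrt(rowSums(dir_i^2))
      f_i <- result$F_max / n_i
      out[[length(out) + 1]] <- data.frame(
        node = i_nodes, fx = f_i * dir_i[, 1], fy = f_i * dir_i[, 2],
        fz = f_i * dir_i[, 3], muscle = muscle$name, side = side)
    }
  }
  do.call(rbind, out)
}

#' Assemble the full muscle loading for a specimen on a mesh
#'
#' Builds and concatenates the force vectors of all muscles in the list
#' (bilaterally, two-nodes method).
#'
#' @param mesh a `skull_mesh`.
#' @param muscles list of [jaw_muscle()] objects (see
#'   [specimen_muscles()]).
#' @param policy a [node_count_policy()].
#' @param muscle_stress_P specific muscle stress, MPa.
#' @param apply,exclude passed to [build_force_vectors()].
#' @return data.frame of nodal forces for all muscles.
#' @export
muscle_loading <- function(mesh, muscles, policy = node_count_policy(),
                           muscle_stress_P = 0.3, apply = "origin",
                           exclude = NULL) {
  do.call(rbind, lapply(muscles, function(m) {
    build_force_vectors(mesh, m, muscle_force(m, muscle_stress_P), policy,
                        apply = apply, exclude = exclude)
  }))
}

#' Construct the FE load case for one bite position
#'
#' Fixes the requested bite node set together with both basicranium
#' patches (all translational freedoms, emulating bilateral biting with a
#' constrained braincase) and applies the full bilateral muscle loading.
#'
#' @param mesh a `skull_mesh`.
#' @param muscles list of [jaw_muscle()] objects.
#' @param bite one of `"bite_anterior"`, `"bite_mid"`, `"bite_posterior"`,
#'   or the name of any node set to use as the bite constraint.
#' @param policy a [node_count_policy()].
#' @param muscle_stress_P specific muscle stress, MPa.
#' @param label optional case label; default `<morphotype>:<bite>`.
#' @param apply passed to [build_force_vectors()].
#' @return an [fe_load_case()].
#' @export
bite_load_case <- function(mesh, muscles, bite, policy = node_count_policy(),
                           muscle_stress_P = 0.3, label = NULL,
                           apply = "origin") {
  if (is.null(mesh$node_sets[[bite]])) {
    stop("mesh has no node set '", bite, "'", call. = FALSE)
  }
  fixed <- c(mesh$node_sets[[bite]],
             mesh$node_sets$basicranium_left,
             mesh$node_sets$basicranium_right)
  # constrained nodes are removed from the attachment candidates before
  # subset selection: a node cannot be both loaded and fixed
  forces <- muscle_loading(mesh, muscles, policy, muscle_stress_P,
                           apply = apply, exclude = fixed)
  fe_load_case(forces, fixed,
               label = label %||% paste0(mesh$params$label, ":", bite))
}
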