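#' Rigid-body sub-process operator
#'
#' Binds the rigid parameters (3 rotation-vector components about a center
#' of rotation, plus 3 translation components or 1 along a fixed axis) of
#' one mobile unit to an objective context. The objective of the rigid
#' family is the nonbonded interaction energy *between* the rigid bodies in
#' context; intra-cuboid pairs are excluded.
#'
#' @param pa a `parameterized_assembly`.
#' @param unit mobile unit label.
#' @param center a [rotation_center()] or length-3 point.
#' @param translation `"vector3"` (free translation) or `"axis1"` (scalar
#'   along `axis`).
#' @param axis unit axis for `"axis1"` translation.
#' @param context list of unit-label pairs whose interaction enters the
#'   objective; by default all pairs between `unit` and the other units.
#' @return an `operator_spec` (family `RIGID`).
#' @export
rigid_operator <- function(pa, unit, center, translation = "vector3",
                           axis = NULL, context = NULL) {
  if (inherits(center, "rotation_center")) center <- center$point
  if (is.null(center) || length(center) != 3L || !all(is.finite(center))) {
    stop("configuration error: undefined center of rotation")
  }
  labels <- unit_labels(pa)
  stopifnot(unit %in% labels)
  if (is.null(context)) {
    context <- lapply(setdiff(labels, unit), function(v) c(unit, v))
  }
  structure(list(family = "RIGID", unit = unit, center = as.numeric(center),
                 translation = translation, axis = axis, context = context),
            class = "operator_spec")
}

#' Carboxamide-rotation sub-process operator
#'
#' One parameter: the dihedral angle of an Asn/Gln carboxamide group about
#' the carbon-carbon bond next to it (Cbeta-Cgamma for Asn, Cgamma-Cdelta
#' for Gln). Rotating the parameter moves only the terminal amide atoms
#' (O, N and the amide hydrogens); the axis-proximal carbon stays fixed.
#' The objective accounts for the side-chain bonded terms that change with
#' the dihedral plus all nonbonded terms involving the moved atoms within
#' the chosen environment -- the residue's own domain (`context = "unit"`)
#' or the whole assembly (`context = "assembly"`), intra-cuboid pairs
#' included.
#'
#' @param pa a `parameterized_assembly`.
#' @param chain,resno,insert residue selector; must be Asn or Gln with
#'   amide hydrogens placed.
#' @param context objective environment.
#' @return an `operator_spec` (family `CARBOXAMIDE`).
#' @export
carboxamide_operator <- function(pa, chain, resno, insert = "",
                                 context = c("assembly", "unit")) {
  context <- match.arg(context)
  ax <- carboxamide_axis(pa, chain, resno, insert)  # errors on wrong residue
  if (length(ax$moved) < 2L) {
    stop("incomplete residue ", chain, ":", resno,
         ": amide hydrogens not placed")
  }
  structure(list(family = "CARBOXAMIDE", chain = chain, resno = resno,
                 insert = insert, context = context, axis_info = ax),
            class = "operator_spec")
}

#' Position-restraint sub-process operator
#'
#' Adds a flat-bottom harmonic penalty on the displacement of a unit's
#' anchor point (its center of rotation) from a reference position; zero
#' inside the threshold. Contributes additively to the total objective.
#'
#' @param pa a `parameterized_assembly`.
#' @param unit restrained unit label.
#' @param spec a [restraint_spec()].
#' @param anchor length-3 anchor point carried by the unit's rigid motion;
#'   defaults to the spec's reference point.
#' @return an `operator_spec` (family `RESTRAINT`).
#' @export
restraint_operator <- function(pa, unit, spec, anchor = NULL) {
  stopifnot(inherits(spec, "restraint_spec"), unit %in% unit_labels(pa))
  structure(list(family = "RESTRAINT", unit = unit, spec = spec,
                 anchor = as.numeric(anchor %||% spec$reference_point)),
            class = "operator_spec")
}

rotate_about_axis <- function(xyz, point, axis, angle) {
  R <- rotation_from_vector(axis * angle)
  sweep(sweep(xyz, 2L, point) %*% t(R), 2L, point, "+")
}

#' Bind sub-process operators into one global objective
#'
#' Concurrently active operators share a single objective so nonbonded
#' pairs are never double-counted: inter-unit pairs come from the rigid
#' contexts, carboxamide operators add the pairs of their moved atoms
#' within their environment that the rigid contexts do not already cover,
#' and restraints are additive. Parameters are concatenated (per rigid
#' unit: 3 rotation + translation components; per carboxamide: 1 dihedral),
#' and the analytic gradient is assembled by the chain rule from per-atom
#' forces and the exponential-map derivatives.
#'
#' @param pa a `parameterized_assembly`.
#' @param operators list of `operator_spec`s.
#' @param opts an [energy_options()].
#' @return an `objective_context`: list with `fn`, `gr`, `apply` (theta to
#'   coordinates), `npar`, and `slices` naming each operator's parameter
#'   block.
#' @export
make_objective <- function(pa, operators, opts = energy_options()) {
  stopifnot(all(vapply(operators, inherits, TRUE, "operator_spec")))
  base <- assembly_xyz(pa)
  fams <- vapply(operators, `[[`, "", "family")
  rigid_ops <- operators[fams == "RIGID"]
  carb_ops <- operators[fams == "CARBOXAMIDE"]
  restr_ops <- operators[fams == "RESTRAINT"]

  rigid_units <- vapply(rigid_ops, `[[`, "", "unit")
  if (anyDuplicated(rigid_units)) {
    stop("configuration error: several rigid operators target one unit")
  }

  # parameter layout
  slices <- list()
  off <- 0L
  for (k in seq_along(rigid_ops)) {
    np <- 3L + if (rigid_ops[[k]]$translation == "axis1") 1L else 3L
    slices[[paste0("rigid_", rigid_units[k])]] <- off + seq_len(np)
    off <- off + np
  }
  for (k in seq_along(carb_ops)) {
    slices[[paste0("carboxamide_", carb_ops[[k]]$chain, "_",
                   carb_ops[[k]]$resno)]] <- off + 1L
    off <- off + 1L
  }
  npar <- off

  unit_idx <- lapply(setNames(nm = unit_labels(pa)), unit_indices, assembly = pa)

  # inter-unit pair blocks from the rigid contexts, each unit pair once
  pair_keys <- character()
  inter_pairs <- list()
  for (op in rigid_ops) {
    for (pr in op$context) {
      pr <- sort(pr)
      key <- paste(pr, collapse = "-")
      if (!key %in% pair_keys && all(pr %in% names(unit_idx))) {
        pair_keys <- c(pair_keys, key)
        inter_pairs[[key]] <- pr
      }
    }
  }
  covered <- lapply(inter_pairs, identity)
  blocks <- lapply(inter_pairs, function(pr) {
    pair_block(pa, unit_idx[[pr[1]]], unit_idx[[pr[2]]], opts)
  })

  # carboxamide environment blocks (pairs not already covered above)
  carb_info <- list()
  seen_moved <- integer()
  if (length(carb_ops)) {
    ctxs <- vapply(carb_ops, `[[`, "", "context")
    if (length(unique(ctxs)) > 1L) {
      stop("configuration error: mixed carboxamide contexts in one objective")
    }
  }
  for (k in seq_along(carb_ops)) {
    op <- carb_ops[[k]]
    ax <- op$axis_info
    own_unit <- ax$unit
    if (op$context == "unit") {
      env <- unit_idx[[own_unit]]
    } else {
      env <- unit_idx[[own_unit]]
      for (v in setdiff(names(unit_idx), own_unit)) {
        key_uv <- paste(sort(c(own_unit, v)), collapse = "-")
        if (!key_uv %in% pair_keys) env <- c(env, unit_idx[[v]])
      }
    }
    env <- setdiff(env, c(ax$moved, seen_moved))
    blocks[[paste0("carb_", k)]] <- pair_block(pa, ax$moved, env, opts)
    seen_moved <- c(seen_moved, ax$moved)
    carb_info[[k]] <- list(
      moved = ax$moved,
      point = base[ax$b_prox, ],
      axis = {
        a <- base[ax$b_dist, ] - base[ax$b_prox, ]
        a / sqrt(sum(a^2))
      },
      unit = own_unit,
      terms = axis_torsion_terms(pa, ax),
      slice = slices[[paste0("carboxamide_", op$chain, "_", op$resno)]])
  }
  big_block <- do.call(merge_blocks, unname(blocks))

  rigid_info <- lapply(seq_along(rigid_ops), function(k) {
    op <- rigid_ops[[k]]
    list(unit = op$unit, idx = unit_idx[[op$unit]], center = op$center,
         translation = op$translation, axis = op$axis,
         slice = slices[[paste0("rigid_", op$unit)]])
  })
  names(rigid_info) <- rigid_units

  restr_info <- lapply(restr_ops, function(op) {
    list(unit = op$unit, spec = op$spec, anchor = op$anchor)
  })

  decode_rigid <- function(info, theta) {
    th <- theta[info$slice]
    v <- th[1:3]
    t_vec <- if (info$translation == "axis1") th[4] * info$axis else th[4:6]
    list(v = v, R = rotation_from_vector(v), t = t_vec)
  }

  # Y: coordinates after dihedral rotations, before rigid motion
  build_coords <- function(theta) {
    Y <- base
    for (ci in carb_info) {
      delta <- theta[ci$slice]
      if (delta != 0) {
        Y[ci$moved, ] <- rotate_about_axis(Y[ci$moved, , drop = FALSE],
                                           ci$point, ci$axis, delta)
      }
    }
    X <- Y
    rig <- list()
    for (ri in rigid_info) {
      d <- decode_rigid(ri, theta)
      X[ri$idx, ] <- sweep(sweep(Y[ri$idx, , drop = FALSE], 2L, ri$center) %*%
                             t(d$R), 2L, ri$center + d$t, "+")
      rig[[ri$unit]] <- d
    }
    list(X = X, Y = Y, rig = rig)
  }

  memo <- new.env(parent = emptyenv())
  coords_for <- function(theta) {
    if (!is.null(memo$theta) && identical(memo$theta, theta)) return(memo$cc)
    cc <- build_coords(theta)
    memo$theta <- theta
    memo$cc <- cc
    cc
  }

  transform_point <- function(p, rig_d, center) {
    if (is.null(rig_d)) return(p)
    as.numeric(rig_d$R %*% (p - center)) + center + rig_d$t
  }

  energy_extras <- function(cc) {
    e <- 0
    for (ci in carb_info) {
      e <- e + torsion_terms_energy(cc$X, ci$terms)$energy
    }
    for (rs in restr_info) {
      ri <- rigid_info[[rs$unit]]
      anchor_cur <- if (is.null(ri)) rs$anchor else
        transform_point(rs$anchor, cc$rig[[rs$unit]], ri$center)
      e <- e + restraint_energy(anchor_cur, rs$spec)$energy
    }
    e
  }

  fn <- function(theta) {
    cc <- coords_for(theta)
    block_energy(cc$X, big_block, opts) + energy_extras(cc)
  }

  gr <- function(theta) {
    cc <- coords_for(theta)
    bg <- block_energy_gradient(cc$X, big_block, opts)
    G <- bg$gradient
    grad <- numeric(npar)
    # restraint anchors feed the rigid chain rule: collect, per restrained
    # unit, the (pre-motion anchor, dE/danchor) contributions
    anchor_terms <- list()
    for (rs in restr_info) {
      ri <- rigid_info[[rs$unit]]
      anchor_cur <- if (is.null(ri)) rs$anchor else
        transform_point(rs$anchor, cc$rig[[rs$unit]], ri$center)
      re <- restraint_energy(anchor_cur, rs$spec)
      if (!is.null(ri) && any(re$gradient != 0)) {
        anchor_terms[[rs$unit]] <- c(anchor_terms[[rs$unit]],
                                     list(list(anchor = rs$anchor,
                                               g = re$gradient)))
      }
    }
    for (ri in rigid_info) {
      d <- cc$rig[[ri$unit]]
      Gu <- G[ri$idx, , drop = FALSE]
      g_sum <- colSums(Gu)
      a_terms <- anchor_terms[[ri$unit]]
      for (at in a_terms) g_sum <- g_sum + at$g
      dR <- drotation_dvector(d$v, d$R)
      Yc <- sweep(cc$Y[ri$idx, , drop = FALSE], 2L, ri$center)
      g_rot <- vapply(1:3, function(k) {
        val <- sum(Gu * (Yc %*% t(dR[[k]])))
        for (at in a_terms) {
          val <- val + sum(at$g * (dR[[k]] %*% (at$anchor - ri$center)))
        }
        val
      }, numeric(1))
      th <- ri$slice
      grad[th[1:3]] <- g_rot
      if (ri$translation == "axis1") {
        grad[th[4]] <- sum(g_sum * ri$axis)
      } else {
        grad[th[4:6]] <- g_sum
      }
    }
    for (ci in carb_info) {
      Yc <- sweep(cc$Y[ci$moved, , drop = FALSE], 2L, ci$point)
      tangent <- cbind(ci$axis[2] * Yc[, 3] - ci$axis[3] * Yc[, 2],
                       ci$axis[3] * Yc[, 1] - ci$axis[1] * Yc[, 3],
                       ci$axis[1] * Yc[, 2] - ci$axis[2] * Yc[, 1])
      d <- cc$rig[[ci$unit]]
      if (!is.null(d)) tangent <- tangent %*% t(d$R)
      # the amide rotation by +theta decreases the spanning dihedrals by
      # theta (measured from the fixed side), hence the sign
      de <- sum(G[ci$moved, , drop = FALSE] * tangent) -
        torsion_terms_energy(cc$X, ci$terms)$denergy
      grad[ci$slice] <- de
    }
    grad
  }

  structure(list(fn = fn, gr = gr,
                 apply = function(theta) coords_for(theta)$X,
                 npar = npar, slices = slices, blocks = blocks),
            class = "objective_context")
}
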