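centroid <- function(xyz) unname(colMeans(as.matrix(xyz)))

#' Fit an oriented cuboid to an atom selection
#'
#' Reduces a structural unit to an oriented box: center = selection
#' centroid, axes = covariance eigenvectors ordered by descending
#' eigenvalue (axis 1 = long axis), extents = maximum absolute projection
#' onto each axis. Axis signs are canonicalized by requiring a positive
#' projection of the designated reference point (by default the selection
#' point farthest from the center) on axes 1 and 2; axis 3 completes a
#' right-handed frame.
#'
#' @param xyz n x 3 coordinate matrix (at least 4 non-collinear points).
#' @param ref_point optional index of the reference point used for sign
#'   canonicalization.
#' @return object of class `cuboid`: list with `center`, `axes` (3x3,
#'   columns are unit axes), `extents`.
#' @export
fit_cuboid <- function(xyz, ref_point = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 4L) stop("geometry error: need at least 4 points")
  ctr <- centroid(xyz)
  cent <- sweep(xyz, 2L, ctr)
  ev <- eigen(crossprod(cent) / nrow(cent), symmetric = TRUE)
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1e-30)) {
    stop("geometry error: collinear selection, cuboid undefined")
  }
  axes <- ev$vectors  # columns, descending eigenvalue
  if (is.null(ref_point)) {
    ref_point <- which.max(rowSums(cent * cent))
  }
  r <- cent[ref_point, ]
  for (k in 1:2) {
    if (sum(r * axes[, k]) < 0) axes[, k] <- -axes[, k]
  }
  axes[, 3] <- crossprod3(axes[, 1], axes[, 2])
  proj <- cent %*% axes
  structure(list(center = ctr, axes = axes,
                 extents = apply(abs(proj), 2L, max)),
            class = "cuboid")
}

#' Fit the cuboid of one assembly unit
#'
#' Uses the unit's backbone atoms (N, CA, C) as the framework selection, so
#' the box orientation is insensitive to side-chain motion.
#'
#' @param assembly a `tcr_assembly`.
#' @param label unit label.
#' @param selection atom names used for the fit.
#' @return a [fit_cuboid()] result.
#' @export
unit_cuboid <- function(assembly, label, selection = c("N", "CA", "C")) {
  idx <- unit_indices(assembly, label)
  idx <- idx[assembly$atoms$elety[idx] %in% selection]
  fit_cuboid(as.matrix(assembly$atoms[idx, c("x", "y", "z")]))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix from three Euler-angle components
#'
#' Intrinsic decomposition about the reference frame's first, second and
#' third axes in that order (the z-y'-x'' convention under the labeling
#' z = axis 1, y = axis 2, x = axis 3 used throughout the package).
#'
#' @param angles length-3 vector, degrees.
#' @return 3x3 rotation matrix.
#' @export
angles_to_matrix <- function(angles) {
  a <- deg2rad(angles)
  rotation_from_vector(c(a[1], 0, 0)) %*%
    rotation_from_vector(c(0, a[2], 0)) %*%
    rotation_from_vector(c(0, 0, a[3]))
}

#' Euler-angle components of a mobile orientation
#'
#' Decomposes the rotation carrying the reference axes onto the mobile
#' axes in the package's fixed intrinsic 1-2'-3'' convention. Near gimbal
#' lock (second angle near +-90 degrees) the result is flagged and the
#' first/third angles canonicalized (third set to 0).
#'
#' @param mobile 3x3 mobile axes (columns) or a `cuboid`.
#' @param reference 3x3 reference axes (columns) or a `cuboid`; identity by
#'   default (the Valpha frame).
#' @return object of class `orientation_angles`: numeric length 3 (degrees)
#'   with attribute `gimbal`.
#' @export
measure_orientation <- function(mobile, reference = diag(3)) {
  if (inherits(mobile, "cuboid")) mobile <- mobile$axes
  if (inherits(reference, "cuboid")) reference <- reference$axes
  R <- t(reference) %*% mobile
  s2 <- R[1, 3]
  gimbal <- abs(abs(s2) - 1) < 1e-9
  if (gimbal) {
    a2 <- asin(max(-1, min(1, s2)))
    a1 <- atan2(R[3, 2], R[2, 2]) * sign(s2)
    a3 <- 0
  } else {
    a2 <- asin(s2)
    a1 <- atan2(-R[2, 3], R[3, 3])
    a3 <- atan2(-R[1, 2], R[1, 1])
  }
  structure(rad2deg(c(a1, a2, a3)), gimbal = gimbal,
            class = "orientation_angles")
}

#' @export
print.orientation_angles <- function(x, ...) {
  cat(sprintf("orientation (deg): %8.3f %8.3f %8.3f%s\n", x[1], x[2], x[3],
              if (isTRUE(attr(x, "gimbal"))) "  [gimbal]" else ""))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#' @param P,Q n x 3 matrices; returns the rotation `R` and translation `t`
#'   minimizing `|| P R^T + t - Q ||`.
#' @keywords internal
kabsch <- function(P, Q) {
  cp <- centroid(P); cq <- centroid(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

#' Align an assembly to the Valpha reference frame
#'
#' Rigidly transforms the whole assembly so that the named Valpha backbone
#' atoms superpose in the least-squares sense onto a reference. With the
#' default `reference = NULL` the canonical frame is used: the Valpha
#' cuboid center moves to the origin and its axes onto the coordinate axes,
#' which makes orientation angles directly comparable across structures.
#'
#' @param assembly a `tcr_assembly`.
#' @param frame_resno optional residue numbers (within VA) restricting the
#'   frame atoms; all VA residues by default.
#' @param reference optional m x 3 matrix of target coordinates for the
#'   frame atoms (same order), e.g. from a previously aligned structure.
#' @return the aligned assembly; the applied transform is stored in
#'   `meta$alignment` (`list(R, t)`).
#' @export
align_to_va_frame <- function(assembly, frame_resno = NULL, reference = NULL) {
  idx <- unit_indices(assembly, "VA")
  idx <- idx[assembly$atoms$elety[idx] %in% c("N", "CA", "C")]
  if (!is.null(frame_resno)) {
    idx <- idx[assembly$atoms$resno[idx] %in% frame_resno]
  }
  if (length(idx) < 3L) stop("alignment error: fewer than 3 frame atoms")
  P <- as.matrix(assembly$atoms[idx, c("x", "y", "z")])
  if (is.null(reference)) {
    cb <- fit_cuboid(P)
    R <- t(cb$axes)
    t_vec <- as.numeric(-R %*% cb$center)
  } else {
    stopifnot(nrow(reference) == length(idx))
    fit <- kabsch(P, as.matrix(reference))
    R <- fit$R; t_vec <- fit$t
  }
  xyz <- assembly_xyz(assembly) %*% t(R)
  xyz <- sweep(xyz, 2L, t_vec, "+")
  out <- set_assembly_xyz(assembly, xyz)
  out$meta$alignment <- list(R = R, t = t_vec)
  out
}

#' Rotation-center object
#' @param label `"COR_BETA"` or `"COR_MU"`.
#' @param point length-3 coordinates (Angstrom, Valpha frame).
#' @param detail optional provenance (residue ids etc.).
#' @export
rotation_center <- function(label, point, detail = list()) {
  stopifnot(label %in% c("COR_BETA", "COR_MU"), length(point) == 3L,
            all(is.finite(point)))
  structure(list(label = label, point = as.numeric(point), detail = detail),
            class = "rotation_center")
}

carboxamide_centroid <- function(assembly, chain, resno, insert = "") {
  rows <- residue_rows(assembly, chain, resno, insert)
  resid <- assembly$atoms$resid[rows[1]]
  nm <- amide_atom_names(resid)
  heavy <- rows[assembly$atoms$elety[rows] %in% c(nm$c, nm$o, nm$n)]
  if (length(heavy) != 3L) {
    stop("incomplete carboxamide group in ", chain, ":", resno)
  }
  centroid(assembly$atoms[heavy, c("x", "y", "z")])
}

unit_glutamines <- function(assembly, label) {
  idx <- unit_indices(assembly, label)
  res <- unique(assembly$atoms[idx, c("chain", "resno", "insert", "resid")])
  res[res$resid == "GLN", , drop = FALSE]
}

#' Locate the Valpha/Vbeta center of rotation
#'
#' CoR_beta sits in the middle of the conserved hydrogen-bonded interaction
#' between the two interface glutamines (one per variable domain): the
#' midpoint of their carboxamide-group centroids. By default the conserved
#' pair is identified as the Gln pair (one per domain) with the smallest
#' inter-carboxamide distance; pass residue selectors to override.
#'
#' @param assembly a `tcr_assembly` containing VA and VB.
#' @param q_alpha,q_beta optional `list(chain =, resno =, insert =)`
#'   selectors for nonstandard cases.
#' @return a [rotation_center()] labeled `COR_BETA`; `detail` records the
#'   chosen residues. Raises a condition of class `cor_undefined` if either
#'   domain lacks a glutamine.
#' @export
locate_cor_beta <- function(assembly, q_alpha = NULL, q_beta = NULL) {
  pick <- function(unit, override) {
    if (!is.null(override)) {
      override$insert <- override$insert %||% ""
      return(override)
    }
    qs <- unit_glutamines(assembly, unit)
    if (!nrow(qs)) {
      stop(structure(class = c("cor_undefined", "error", "condition"),
                     list(message = paste0("no glutamine in unit ", unit,
                                           "; CoR_beta undefined"),
                          call = sys.call(-1))))
    }
    qs
  }
  qa <- pick("VA", q_alpha)
  qb <- pick("VB", q_beta)
  best <- NULL; best_d <- Inf
  for (i in seq_len(NROW(qa))) {
    for (j in seq_len(NROW(qb))) {
      ca <- carboxamide_centroid(assembly, qa$chain[i], qa$resno[i],
                                 qa$insert[i] %||% "")
      cb <- carboxamide_centroid(assembly, qb$chain[j], qb$resno[j],
                                 qb$insert[j] %||% "")
      d <- sum((ca - cb)^2)
      if (d < best_d) {
        best_d <- d
        best <- list(qa = as.list(qa[i, , drop = FALSE]),
                     qb = as.list(qb[j, , drop = FALSE]),
                     point = (ca + cb) / 2)
      }
    }
  }
  rotation_center("COR_BETA", best$point,
                  detail = list(q_alpha = best$qa, q_beta = best$qb,
                                distance = sqrt(best_d)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the pMHC center of rotation
#'
#' CoR_mu lies at the center of the peptide binding groove, operationalized
#' as the centroid of the peptide's backbone atoms (N, CA, C, O). The
#' peptide chain is taken from the assembly metadata (`peptide_chain`), or
#' defaults to the PMHC chain with the fewest residues. A function of the
#' pMHC coordinates only.
#'
#' @param assembly a `tcr_assembly` with a PMHC unit.
#' @return a [rotation_center()] labeled `COR_MU`.
#' @export
locate_cor_mu <- function(assembly) {
  idx <- unit_indices(assembly, "PMHC")
  if (!length(idx)) {
    stop(structure(class = c("cor_undefined", "error", "condition"),
                   list(message = "no PMHC unit; CoR_mu undefined",
                        call = sys.call(-1))))
  }
  pep <- assembly$meta$peptide_chain
  if (is.null(pep)) {
    chains <- assembly$atoms$chain[idx]
    nres <- vapply(unique(chains), function(ch) {
      length(unique(assembly$atoms$resno[idx][chains == ch]))
    }, numeric(1))
    pep <- names(nres)[which.min(nres)]
  }
  bb <- idx[assembly$atoms$chain[idx] == pep &
              assembly$atoms$elety[idx] %in% c("N", "CA", "C", "O")]
  if (!length(bb)) {
    stop(structure(class = c("cor_undefined", "error", "condition"),
                   list(message = "no peptide backbone atoms; CoR_mu undefined",
                        call = sys.call(-1))))
  }
  rotation_center("COR_MU", centroid(assembly$atoms[bb, c("x", "y", "z")]),
                  detail = list(peptide_chain = pep))
}

#' Packaged default Vbeta start rotations
#' @return 11 x 3 matrix of rotation-vector components (degrees) along the
#'   Vbeta cuboid axes.
#' @export
default_start_rotations <- function() {
  path <- system.file("extdata", "start_orientations.tsv", package = "tcrdom")
  as.matrix(utils::read.table(path, comment.char = "#",
                              col.names = c("a1", "a2", "a3")))
}

#' Generate the starting orientations of the Vbeta domain
#'
#' Each start applies one configured rotation vector (degrees, components
#' along the Vbeta cuboid axes) to the Vbeta unit about CoR_beta. The
#' default set holds 11 orientations covering the observed range of
#' variable-domain packing angles, the identity first. When CoR_beta is
#' undefined (a domain without the conserved glutamine) a single identity
#' start is returned with a warning.
#'
#' @param assembly a `tcr_assembly`.
#' @param rotations k x 3 matrix of rotation vectors, degrees;
#'   [default_start_rotations()] by default.
#' @param cor optional precomputed [rotation_center()].
#' @return a `start_set`: list with `assemblies` (list of `tcr_assembly`)
#'   and `provenance` (data frame of applied rotations).
#' @export
generate_start_orientations <- function(assembly,
                                        rotations = default_start_rotations(),
                                        cor = NULL) {
  rotations <- as.matrix(rotations)
  if (!nrow(rotations)) stop("configuration error: empty start-rotation set")
  if (is.null(cor)) {
    cor <- tryCatch(locate_cor_beta(assembly), cor_undefined = function(e) {
      warning("CoR_beta undefined; falling back to a single identity start")
      NULL
    })
    if (is.null(cor)) {
      return(structure(list(assemblies = list(assembly),
                            provenance = data.frame(a1 = 0, a2 = 0, a3 = 0)),
                       class = "start_set"))
    }
  }
  axes <- unit_cuboid(assembly, "VB")$axes
  vb <- unit_indices(assembly, "VB")
  xyz <- assembly_xyz(assembly)
  assemblies <- vector("list", nrow(rotations))
  for (k in seq_len(nrow(rotations))) {
    v_world <- as.numeric(axes %*% deg2rad(rotations[k, ]))
    pose <- rigid_pose(rotation = v_world)
    new_xyz <- xyz
    new_xyz[vb, ] <- apply_rigid_pose(xyz[vb, , drop = FALSE], pose, cor$point)
    assemblies[[k]] <- set_assembly_xyz(assembly, new_xyz)
  }
  structure(list(assemblies = assemblies,
                 provenance = data.frame(a1 = rotations[, 1],
                                         a2 = rotations[, 2],
                                         a3 = rotations[, 3]),
                 cor = cor),
            class = "start_set")
}

#' Pre-place the pMHC unit away from the TCR
#'
#' Puts the pMHC in the general (zero) orientation and translates it by
#' `offset` along the packaged translation axis, pointing away from the
#' TCR. The axis is the normal of the MHC platform beta-sheet plane,
#' stored in the assembly metadata (`pmhc_axis`); synthetic fixtures embed
#' theirs at construction.
#'
#' @param assembly a `tcr_assembly` with a PMHC unit, already in the
#'   general orientation unless `general_rotation` is given.
#' @param offset translation distance in Angstrom (default 15).
#' @param axis optional length-3 translation axis overriding the metadata.
#' @param general_rotation optional 3x3 matrix re-orienting the pMHC about
#'   CoR_mu before the translation.
#' @return the transformed assembly.
#' @export
preplace_pmhc <- function(assembly, offset = 15, axis = NULL,
                          general_rotation = NULL) {
  idx <- unit_indices(assembly, "PMHC")
  if (!length(idx)) stop("configuration error: assembly has no PMHC unit")
  axis <- axis %||% assembly$meta$pmhc_axis
  if (is.null(axis)) {
    stop("configuration error: no pMHC translation axis available")
  }
  axis <- axis / sqrt(sum(axis^2))
  cor_mu <- locate_cor_mu(assembly)
  xyz <- assembly_xyz(assembly)
  if (!is.null(general_rotation)) {
    sub <- sweep(xyz[idx, , drop = FALSE], 2L, cor_mu$point)
    xyz[idx, ] <- sweep(sub %*% t(general_rotation), 2L, cor_mu$point, "+")
  }
  tcr_center <- centroid(xyz[c(unit_indices(assembly, "VA"),
                               unit_indices(assembly, "VB")), , drop = FALSE])
  if (sum(axis * (cor_mu$point - tcr_center)) < 0) axis <- -axis
  xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2L, offset * axis, "+")
  set_assembly_xyz(assembly, xyz)
}

#' Factorial grid of pMHC starting poses
#'
#' Systematically varies the three Euler-angle components of the pMHC
#' orientation about CoR_mu by `+-delta_deg` (three values per axis by
#' default), producing the full factorial grid: 27 poses at the defaults.
#' The central (0, 0, 0) grid point is the input pose.
#'
#' @param assembly a `tcr_assembly` with PMHC.
#' @param delta_deg angular step, degrees (> 0).
#' @param values_per_axis odd number of values per Euler component.
#' @return a `start_set` with `values_per_axis^3` assemblies; provenance
#'   lists the Euler offsets.
#' @export
generate_pmhc_pose_grid <- function(assembly, delta_deg = 5,
                                    values_per_axis = 3) {
  stopifnot(delta_deg > 0, values_per_axis >= 1)
  half <- (values_per_axis - 1) / 2
  vals <- seq(-half, half) * delta_deg
  grid <- expand.grid(a1 = vals, a2 = vals, a3 = vals)
  cor_mu <- locate_cor_mu(assembly)
  idx <- unit_indices(assembly, "PMHC")
  xyz <- assembly_xyz(assembly)
  assemblies <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    R <- angles_to_matrix(as.numeric(grid[k, ]))
    sub <- sweep(xyz[idx, , drop = FALSE], 2L, cor_mu$point)
    new_xyz <- xyz
    new_xyz[idx, ] <- sweep(sub %*% t(R), 2L, cor_mu$point, "+")
    assemblies[[k]] <- set_assembly_xyz(assembly, new_xyz)
  }
  structure(list(assemblies = assemblies, provenance = grid, cor = cor_mu),
            class = "start_set")
}

#' Orientation report for an assembly
#'
#' One row per assembly: the three Euler-angle components of the Vbeta
#' cuboid relative to the Valpha cuboid, CoR_beta coordinates, and (when a
#' pMHC unit is present) the pMHC orientation and CoR_mu. Suitable for
#' writing with [utils::write.csv()].
#'
#' @param assembly a `tcr_assembly`.
#' @param id row label.
#' @return one-row data frame.
#' @export
orientation_report <- function(assembly, id = assembly$meta$source %||% "model") {
  cva <- unit_cuboid(assembly, "VA")
  cvb <- unit_cuboid(assembly, "VB")
  ang <- measure_orientation(cvb, cva)
  cor_b <- tryCatch(locate_cor_beta(assembly)$point,
                    cor_undefined = function(e) c(NA, NA, NA))
  out <- data.frame(id = id, vb_a1 = ang[1], vb_a2 = ang[2], vb_a3 = ang[3],
                    corb_x = cor_b[1], corb_y = cor_b[2], corb_z = cor_b[3],
                    stringsAsFactors = FALSE)
  if ("PMHC" %in% unit_labels(assembly)) {
    cp <- unit_cuboid(assembly, "PMHC")
    angp <- measure_orientation(cp, cva)
    cor_m <- locate_cor_mu(assembly)$point
    out$pmhc_a1 <- angp[1]; out$pmhc_a2 <- angp[2]; out$pmhc_a3 <- angp[3]
    out$corm_x <- cor_m[1]; out$corm_y <- cor_m[2]; out$corm_z <- cor_m[3]
  }
  out
}
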