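#' Correct the flip state of one Asn/Gln within its own domain
#'
#' Stage-one correction of a possibly misassigned carboxamide: only two
#' orientations are considered, the original one and a 180-degree rotation,
#' scored against the residue's own domain only. The lower-energy state is
#' selected (ties kept original) and refined by up to `max_steps` BFGS
#' steps of the single dihedral parameter.
#'
#' @param pa a `parameterized_assembly`.
#' @param chain,resno,insert residue selector (Asn or Gln, amide hydrogens
#'   placed).
#' @param opts an [energy_options()].
#' @param max_steps refinement step cap (default 30).
#' @param state_tol_deg half-width (degrees) for calling the final angle
#'   `original` / `flipped` rather than `intermediate`.
#' @return list with the updated `assembly` and a one-row `report` data
#'   frame (`flip_report`): residue id, chosen state, final angle, energies
#'   before/after.
#' @export
correct_flip_single_domain <- function(pa, chain, resno, insert = "",
                                       opts = energy_options(),
                                       max_steps = 30L, state_tol_deg = 15) {
  op <- carboxamide_operator(pa, chain, resno, insert, context = "unit")
  obj <- make_objective(pa, list(op), opts)
  e_orig <- obj$fn(0)
  e_flip <- obj$fn(pi)
  start <- if (e_flip < e_orig - 1e-12) pi else 0
  res <- bfgs_minimize(obj$fn, obj$gr, start, max_steps = max_steps,
                       grad_tol = 1e-4)
  pa2 <- set_assembly_xyz(pa, obj$apply(res$par))
  ang <- wrap_angle_deg(rad2deg(res$par))
  state <- classify_flip_angle(ang, state_tol_deg)
  report <- data.frame(chain = chain, resno = resno, insert = insert,
                       resid = pa$atoms$resid[residue_rows(pa, chain, resno,
                                                           insert)][1],
                       initial_state = "original", chosen_state = state,
                       angle_deg = ang,
                       energy_before = e_orig, energy_after = res$value,
                       iterations = res$iterations,
                       stringsAsFactors = FALSE)
  class(report) <- c("flip_report", class(report))
  list(assembly = pa2, report = report)
}

wrap_angle_deg <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

classify_flip_angle <- function(angle_deg, tol = 15) {
  if (abs(angle_deg) <= tol) "original"
  else if (abs(abs(angle_deg) - 180) <= tol) "flipped"
  else sprintf("intermediate(%.1f)", angle_deg)
}

#' Single-domain flip correction for every Asn/Gln of an assembly
#'
#' Convenience driver behind the standalone correction tool: applies
#' [correct_flip_single_domain()] to all (or a given list of) Asn/Gln
#' residues, each in its own domain context.
#'
#' @param pa a `parameterized_assembly` with amide hydrogens placed.
#' @param residues optional data frame with columns `chain`, `resno`
#'   (optionally `insert`) restricting the set.
#' @param opts an [energy_options()].
#' @param max_steps per-residue refinement cap.
#' @return list with the corrected `assembly` and the combined `report`.
#' @export
correct_flip_all <- function(pa, residues = NULL, opts = energy_options(),
                             max_steps = 30L) {
  if (is.null(residues)) {
    res <- unique(pa$atoms[pa$atoms$resid %in% c("ASN", "GLN"),
                           c("chain", "resno", "insert")])
  } else {
    res <- residues
    if (is.null(res$insert)) res$insert <- ""
  }
  reports <- list()
  for (k in seq_len(nrow(res))) {
    out <- correct_flip_single_domain(pa, res$chain[k], res$resno[k],
                                      res$insert[k], opts, max_steps)
    pa <- out$assembly
    reports[[k]] <- out$report
  }
  list(assembly = pa, report = do.call(rbind, reports))
}

#' Joint sampling of the two conserved interface glutamines
#'
#' Stage-two (bifurcation) correction: the orientations of the two central
#' Q residues are explicitly sampled in the context of the whole assembly
#' (intra- and inter-unit interactions) on a full factorial grid with step
#' `step_deg` -- (360/step)^2 combinations, 400 at the default 18 degrees.
#' The lowest-energy combination is selected and refined by up to
#' `max_steps` joint BFGS steps. Intermediate (non-parallel) final states
#' are permitted, which is what resolves bifurcated Q-Q pairings that
#' two-state flippers cannot.
#'
#' @param pa a `parameterized_assembly`.
#' @param q_alpha,q_beta `list(chain =, resno =, insert =)` selectors of
#'   the two glutamines; if either is `NULL` or absent the correction is
#'   skipped with a warning and the assembly returned unchanged.
#' @param step_deg grid step in degrees (divides 360).
#' @param opts an [energy_options()].
#' @param max_steps refinement cap (default 30).
#' @return list with the updated `assembly`, the `grid` (data frame of the
#'   sampled angle pairs and energies), the chosen grid point, and the
#'   refinement `opt_result`; or the unchanged assembly with `skipped =
#'   TRUE`.
#' @export
optimize_qq_bifurcation <- function(pa, q_alpha, q_beta, step_deg = 18,
                                    opts = energy_options(),
                                    max_steps = 30L) {
  if (is.null(q_alpha) || is.null(q_beta)) {
    warning("conserved glutamine pair unavailable; Q-Q correction skipped")
    return(list(assembly = pa, skipped = TRUE))
  }
  ops <- list(
    carboxamide_operator(pa, q_alpha$chain, q_alpha$resno,
                         q_alpha$insert %||% "", context = "assembly"),
    carboxamide_operator(pa, q_beta$chain, q_beta$resno,
                         q_beta$insert %||% "", context = "assembly"))
  obj <- make_objective(pa, ops, opts)
  angles <- deg2rad(seq(0, 360 - step_deg, by = step_deg))
  grid <- expand.grid(a_alpha = angles, a_beta = angles)
  grid$energy <- vapply(seq_len(nrow(grid)), function(k) {
    obj$fn(c(grid$a_alpha[k], grid$a_beta[k]))
  }, numeric(1))
  best <- which.min(grid$energy)
  res <- bfgs_minimize(obj$fn, obj$gr,
                       c(grid$a_alpha[best], grid$a_beta[best]),
                       max_steps = max_steps, grad_tol = 1e-4)
  list(assembly = set_assembly_xyz(pa, obj$apply(res$par)),
       grid = grid, best = grid[best, , drop = FALSE],
       opt_result = res, skipped = FALSE)
}

#' Classify a carboxamide flip state against a reference
#'
#' Compares the carboxamide group of a model residue with the same residue
#' in a reference structure. If the two carboxamide planes make an angle
#' above `bifurcation_deg` the pairing is `bifurcated` (associated in a
#' roughly perpendicular manner); otherwise the O/N assignment is checked:
#' the heavy-atom labeling (identity or O/N-swapped) with the smaller
#' positional deviation decides `paired` versus `mispaired`.
#'
#' @param model,reference `tcr_assembly` objects containing the residue.
#' @param chain,resno,insert residue selector (Asn or Gln).
#' @param bifurcation_deg plane-angle threshold, degrees (default 60).
#' @return one of `"paired"`, `"mispaired"`, `"bifurcated"`.
#' @export
compare_flip_state <- function(model, reference, chain, resno, insert = "",
                               bifurcation_deg = 60) {
  triad <- function(a) {
    rows <- residue_rows(a, chain, resno, insert)
    if (!length(rows)) stop("residue ", chain, ":", resno, " not found")
    nm <- amide_atom_names(a$atoms$resid[rows[1]])
    get <- function(name) {
      r <- rows[match(name, a$atoms$elety[rows])]
      if (is.na(r)) stop("incomplete residue ", chain, ":", resno)
      as.numeric(a$atoms[r, c("x", "y", "z")])
    }
    list(C = get(nm$c), O = get(nm$o), N = get(nm$n))
  }
  m <- triad(model); r <- triad(reference)
  nrm <- function(t) {
    v <- crossprod3(t$O - t$C, t$N - t$C)
    v / sqrt(sum(v^2))
  }
  ang <- acos(min(1, abs(sum(nrm(m) * nrm(r)))))
  if (rad2deg(ang) > bifurcation_deg) return("bifurcated")
  dev_same <- sum((m$O - r$O)^2) + sum((m$N - r$N)^2)
  dev_swap <- sum((m$O - r$N)^2) + sum((m$N - r$O)^2)
  if (dev_same <= dev_swap) "paired" else "mispaired"
}
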