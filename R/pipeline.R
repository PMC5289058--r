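#' Pipeline configuration
#'
#' Collects every scheduling constant of the remodeling pipeline. The
#' defaults are the standard protocol: 11 Vbeta starting orientations,
#' two-stage Q-flip correction on, position restraints on with thresholds
#' 7.5 Angstrom (Vbeta) and 13.0 Angstrom (pMHC), step limits 30 (single-Q
#' refinement), 150 (pMHC pre-placement), 30 (Q-Q refinement), 50
#' (preliminary concurrent) and 2950 (main concurrent), an 18-degree Q-Q
#' sampling step, a 15 Angstrom pMHC pre-placement offset and a 2 Angstrom
#' success threshold.
#'
#' @param mode `"TCR"` (Valpha/Vbeta only) or `"TCRPMHC"`.
#' @param start_rotations k x 3 matrix of Vbeta start rotation vectors
#'   (degrees, cuboid-axis components); [default_start_rotations()] by
#'   default.
#' @param qflip enable the two-stage carboxamide correction.
#' @param restraints enable the rigid-body position restraints.
#' @param vb_threshold,pmhc_threshold restraint thresholds (Angstrom).
#' @param restraint_k harmonic force constant (kcal/mol/A^2).
#' @param steps named list of step limits (`single_q`, `preplace`, `qq`,
#'   `concurrent_pre`, `concurrent_main`).
#' @param qq_step_deg Q-Q sampling grid step (degrees).
#' @param pmhc_offset pre-placement translation distance (Angstrom).
#' @param rmsd_threshold success threshold (Angstrom).
#' @param grad_tol BFGS gradient tolerance.
#' @param energy an [energy_options()].
#' @param preset optional diagnostic preset: `"T1"` (crystal pMHC
#'   orientation, no translation), `"T2"` (crystal orientation, with
#'   translation) or `"T3"` (general orientation, with translation); each
#'   runs a single crystal-orientation Vbeta start.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("TCR", "TCRPMHC"),
                            start_rotations = default_start_rotations(),
                            qflip = TRUE, restraints = TRUE,
                            vb_threshold = 7.5, pmhc_threshold = 13.0,
                            restraint_k = 10,
                            steps = list(single_q = 30L, preplace = 150L,
                                         qq = 30L, concurrent_pre = 50L,
                                         concurrent_main = 2950L),
                            qq_step_deg = 18, pmhc_offset = 15,
                            rmsd_threshold = 2, grad_tol = 1e-3,
                            energy = energy_options(),
                            preset = c("none", "T1", "T2", "T3")) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  if (preset != "none") {
    mode <- "TCRPMHC"
    start_rotations <- matrix(0, 1L, 3L)
    if (preset == "T1") pmhc_offset <- 0
  }
  stopifnot(vb_threshold > 0, pmhc_threshold > 0, restraint_k >= 0,
            all(unlist(steps) >= 0), qq_step_deg > 0, pmhc_offset >= 0,
            rmsd_threshold > 0)
  structure(list(mode = mode, start_rotations = as.matrix(start_rotations),
                 qflip = qflip, restraints = restraints,
                 vb_threshold = vb_threshold,
                 pmhc_threshold = pmhc_threshold,
                 restraint_k = restraint_k, steps = steps,
                 qq_step_deg = qq_step_deg, pmhc_offset = pmhc_offset,
                 rmsd_threshold = rmsd_threshold, grad_tol = grad_tol,
                 energy = energy, preset = preset),
            class = "pipeline_config")
}

#' Read a pipeline configuration file (YAML)
#'
#' Scalar fields override the defaults of [pipeline_config()];
#' `start_rotations` may be given as a list of 3-vectors (degrees).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$start_rotations)) {
    raw$start_rotations <- do.call(rbind, raw$start_rotations)
  }
  if (!is.null(raw$energy)) raw$energy <- do.call(energy_options, raw$energy)
  do.call(pipeline_config, raw)
}

#' All-atom RMSD of a model against a reference
#'
#' Root mean square deviation over the atoms of the mobile units (Vbeta,
#' and pMHC when present), computed in the shared fixed Valpha frame
#' without re-superposition so that placement error of the mobile units is
#' measured, not masked. Requires a 1:1 atom correspondence.
#'
#' @param model,reference `tcr_assembly` objects with identical atom
#'   tables.
#' @param units unit labels entering the RMSD; the mobile units by default.
#' @return RMSD in Angstrom.
#' @export
all_atom_rmsd <- function(model, reference,
                          units = intersect(c("VB", "PMHC"),
                                            unit_labels(model))) {
  idx_m <- unlist(lapply(units, unit_indices, assembly = model))
  idx_r <- unlist(lapply(units, unit_indices, assembly = reference))
  if (length(idx_m) != length(idx_r) ||
      !identical(model$atoms$elety[idx_m], reference$atoms$elety[idx_r]) ||
      !identical(model$atoms$resno[idx_m], reference$atoms$resno[idx_r])) {
    stop("correspondence error: model and reference atoms do not match 1:1")
  }
  d <- assembly_xyz(model)[idx_m, , drop = FALSE] -
    assembly_xyz(reference)[idx_r, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

conserved_q_selectors <- function(cor) {
  if (is.null(cor)) return(list(qa = NULL, qb = NULL))
  list(qa = list(chain = cor$detail$q_alpha$chain,
                 resno = cor$detail$q_alpha$resno,
                 insert = cor$detail$q_alpha$insert %||% ""),
       qb = list(chain = cor$detail$q_beta$chain,
                 resno = cor$detail$q_beta$resno,
                 insert = cor$detail$q_beta$insert %||% ""))
}

concurrent_operators <- function(pa, config, cor_b, qsel, cor_mu = NULL) {
  ops <- list()
  ops[[length(ops) + 1L]] <- rigid_operator(pa, "VB", cor_b)
  if (config$mode == "TCRPMHC" && "PMHC" %in% unit_labels(pa)) {
    ops[[length(ops) + 1L]] <- rigid_operator(pa, "PMHC", cor_mu)
  }
  if (config$qflip && !is.null(qsel$qa)) {
    ops[[length(ops) + 1L]] <-
      carboxamide_operator(pa, qsel$qa$chain, qsel$qa$resno, qsel$qa$insert,
                           context = "assembly")
    ops[[length(ops) + 1L]] <-
      carboxamide_operator(pa, qsel$qb$chain, qsel$qb$resno, qsel$qb$insert,
                           context = "assembly")
  }
  if (config$restraints) {
    ops[[length(ops) + 1L]] <- restraint_operator(
      pa, "VB", restraint_spec(cor_b$point, config$vb_threshold,
                               config$restraint_k), anchor = cor_b$point)
    if (config$mode == "TCRPMHC" && "PMHC" %in% unit_labels(pa)) {
      ops[[length(ops) + 1L]] <- restraint_operator(
        pa, "PMHC", restraint_spec(cor_mu$point, config$pmhc_threshold,
                                   config$restraint_k),
        anchor = cor_mu$point)
    }
  }
  ops
}

run_one_start <- function(pa, config, e_units, qsel, reference) {
  opts <- config$energy
  log <- data.frame(step = character(), iterations = integer(),
                    initial = numeric(), final = numeric(),
                    converged = logical(), stringsAsFactors = FALSE)
  push <- function(name, res) {
    log <<- rbind(log, data.frame(step = name, iterations = res$iterations,
                                  initial = res$initial_value,
                                  final = res$value,
                                  converged = res$converged,
                                  stringsAsFactors = FALSE))
  }
  has_pmhc <- config$mode == "TCRPMHC" && "PMHC" %in% unit_labels(pa)

  # step 4: pMHC pre-placement and pre-optimization against the fixed TCR
  if (has_pmhc) {
    if (config$pmhc_offset > 0) {
      pa <- preplace_pmhc(pa, offset = config$pmhc_offset)
    }
    cor_mu <- locate_cor_mu(pa)
    axis <- pa$meta$pmhc_axis %||% c(0, 0, 1)
    op <- rigid_operator(pa, "PMHC", cor_mu, translation = "axis1",
                         axis = axis)
    obj <- make_objective(pa, list(op), opts)
    res <- bfgs_minimize(obj$fn, obj$gr, numeric(4),
                         max_steps = config$steps$preplace,
                         grad_tol = config$grad_tol)
    pa <- set_assembly_xyz(pa, obj$apply(res$par))
    push("pmhc_preplace", res)
  }

  # step 5: Q-Q sampling in the whole-assembly context
  if (config$qflip && !is.null(qsel$qa)) {
    qq <- optimize_qq_bifurcation(pa, qsel$qa, qsel$qb,
                                  step_deg = config$qq_step_deg,
                                  opts = opts, max_steps = config$steps$qq)
    pa <- qq$assembly
    if (!qq$skipped) push("qq_sampling", qq$opt_result)
  }

  # step 6: concurrent rigid-body + carboxamide optimization; restraint
  # references are captured at the start of this step
  cor_b <- tryCatch(locate_cor_beta(pa), cor_undefined = function(e) NULL)
  cor_mu <- if (has_pmhc) locate_cor_mu(pa) else NULL
  if (is.null(cor_b)) {
    cb <- unit_cuboid(pa, "VB")
    cor_b <- rotation_center("COR_BETA", cb$center,
                             detail = list(fallback = "VB cuboid center"))
  }
  qsel_use <- if (config$qflip) qsel else list(qa = NULL, qb = NULL)
  ops <- concurrent_operators(pa, config, cor_b, qsel_use, cor_mu)
  obj <- make_objective(pa, ops, opts)
  res <- bfgs_minimize(obj$fn, obj$gr, numeric(obj$npar),
                       max_steps = config$steps$concurrent_pre,
                       grad_tol = config$grad_tol)
  pa <- set_assembly_xyz(pa, obj$apply(res$par))
  push("concurrent_preliminary", res)

  if (config$qflip && !is.null(qsel$qa)) {
    qq <- optimize_qq_bifurcation(pa, qsel$qa, qsel$qb,
                                  step_deg = config$qq_step_deg,
                                  opts = opts, max_steps = config$steps$qq)
    pa <- qq$assembly
    if (!qq$skipped) push("qq_resampling", qq$opt_result)
  }

  ops <- concurrent_operators(pa, config, cor_b, qsel_use, cor_mu)
  obj <- make_objective(pa, ops, opts)
  res <- bfgs_minimize(obj$fn, obj$gr, numeric(obj$npar),
                       max_steps = config$steps$concurrent_main,
                       grad_tol = config$grad_tol)
  pa <- set_assembly_xyz(pa, obj$apply(res$par))
  push("concurrent_main", res)

  # step 7: binding energy (unit self-energies cached once per run)
  report <- binding_energy(pa, opts, reference_units = e_units)
  rmsd <- if (!is.null(reference)) all_atom_rmsd(pa, reference) else NA_real_
  list(assembly = pa, energy = report, rmsd = rmsd, log = log)
}

#' Remodel a TCR (or TCR-pMHC) assembly
#'
#' Full prediction pipeline: (1) cuboid assembly in the Valpha frame;
#' (2) independent single-domain correction of the two conserved interface
#' glutamines; (3) generation of the Vbeta starting orientations;
#' (4, complex mode) pMHC pre-placement and pre-optimization against the
#' fixed TCR; (5) joint Q-Q sampling in the whole-assembly context;
#' (6) concurrent rigid-body plus carboxamide optimization (preliminary
#' pass, Q-Q resampling, main pass); (7) binding-energy evaluation. One
#' model per starting orientation.
#'
#' @param pa a `parameterized_assembly`, aligned to the Valpha frame.
#' @param config a [pipeline_config()].
#' @param reference optional reference `tcr_assembly` (1:1 atoms) for RMSD
#'   reporting.
#' @return a `model_set`: list of `model_result`s (`assembly`, `energy`,
#'   `rmsd`, `index`, `start`, `log`), with the start-set provenance as an
#'   attribute.
#' @export
run_remodeling <- function(pa, config = pipeline_config(), reference = NULL) {
  if (!inherits(pa, "parameterized_assembly")) {
    stop("assembly is not parameterized; call assign_parameters() first")
  }
  opts <- config$energy
  cor_b <- tryCatch(locate_cor_beta(pa), cor_undefined = function(e) {
    warning("CoR_beta undefined; Q-flip steps will be skipped")
    NULL
  })
  qsel <- conserved_q_selectors(cor_b)

  # step 2: separate Q correction, each in its own domain environment
  if (config$qflip && !is.null(qsel$qa)) {
    for (q in list(qsel$qa, qsel$qb)) {
      out <- correct_flip_single_domain(pa, q$chain, q$resno, q$insert, opts,
                                        max_steps = config$steps$single_q)
      pa <- out$assembly
    }
  }

  # unit self-energies: constant for the run, computed once
  e_units <- vapply(setNames(nm = unit_labels(pa)),
                    function(u) unit_internal_energy(pa, u, opts), numeric(1))

  # step 3: starting orientations
  starts <- generate_start_orientations(pa, config$start_rotations, cor_b)

  results <- vector("list", length(starts$assemblies))
  for (k in seq_along(starts$assemblies)) {
    one <- run_one_start(starts$assemblies[[k]], config, e_units, qsel,
                         reference)
    one$index <- k
    one$start <- as.numeric(starts$provenance[k, ])
    class(one) <- "model_result"
    results[[k]] <- one
  }
  structure(results, class = "model_set",
            provenance = starts$provenance)
}

#' Rank models by binding energy
#'
#' Ascending `E_bind`; ties keep the original model order (stable sort by
#' model index).
#'
#' @param results a `model_set` or list of `model_result`s.
#' @return the reordered list.
#' @export
rank_models <- function(results) {
  stopifnot(length(results) >= 1L)
  e <- vapply(results, function(r) r$energy$E_bind, numeric(1))
  out <- results[order(e, seq_along(e))]
  class(out) <- class(results)
  out
}

#' Evaluate the remodeling success criteria
#'
#' `C_E` (energy criterion): the model with the best binding energy has an
#' RMSD below the threshold. `C_R` (structural criterion): at least one
#' model has an RMSD below the threshold.
#'
#' @param results a `model_set` whose models carry RMSD values.
#' @param rmsd_threshold Angstrom (default 2).
#' @return a `success_verdict`: list with `C_R`, `C_E`,
#'   `best_energy_index`, `best_rmsd_index`, `best_energy_rmsd`,
#'   `best_rmsd`.
#' @export
evaluate_success <- function(results, rmsd_threshold = 2) {
  rmsd <- vapply(results, function(r) r$rmsd, numeric(1))
  if (anyNA(rmsd)) stop("models carry no RMSD; supply a reference structure")
  e <- vapply(results, function(r) r$energy$E_bind, numeric(1))
  ibe <- order(e, seq_along(e))[1L]
  ibr <- which.min(rmsd)
  structure(list(C_R = rmsd[ibr] < rmsd_threshold,
                 C_E = rmsd[ibe] < rmsd_threshold,
                 best_energy_index = ibe, best_rmsd_index = ibr,
                 best_energy_rmsd = rmsd[ibe], best_rmsd = rmsd[ibr]),
            class = "success_verdict")
}

#' @export
print.success_verdict <- function(x, ...) {
  cat(sprintf("C_R: %s (best RMSD %.3f A, model %d)\n",
              x$C_R, x$best_rmsd, x$best_rmsd_index))
  cat(sprintf("C_E: %s (best-energy model %d, RMSD %.3f A)\n",
              x$C_E, x$best_energy_index, x$best_energy_rmsd))
  invisible(x)
}

#' @export
print.model_set <- function(x, ...) {
  e <- vapply(x, function(r) r$energy$E_bind, numeric(1))
  r <- vapply(x, function(r) r$rmsd, numeric(1))
  cat("model_set with", length(x), "models\n")
  print(data.frame(model = seq_along(x), E_bind = round(e, 4),
                   rmsd = round(r, 4)))
  invisible(x)
}

#' Machine-readable run report
#'
#' Per-model binding-energy decomposition, RMSD and per-step optimization
#' log, as a list ready for [jsonlite::write_json()].
#'
#' @param results a `model_set`.
#' @return a list.
#' @export
run_report <- function(results) {
  lapply(results, function(r) {
    list(index = r$index, start = r$start,
         E_bind = r$energy$E_bind, E_complex = r$energy$E_complex,
         E_alpha = r$energy$E_alpha, E_beta = r$energy$E_beta,
         E_mu = r$energy$E_mu, rmsd = r$rmsd,
         steps = r$log)
  })
}
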