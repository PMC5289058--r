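#' Nonbonded energy options
#'
#' Collects the conventions of the packaged OPLS-style parameter table:
#' Coulomb constant 332.0636 kcal A / mol / e^2, vacuum electrostatics
#' (relative dielectric 1), geometric-mean combination for both sigma and
#' epsilon, and 0.5/0.5 scaling of 1-4 pairs. All pairs are summed by
#' default (`cutoff = Inf`); a finite cutoff applies a smooth switching
#' taper over the last `switch_width` Angstrom so gradients stay continuous.
#'
#' @param coulomb_constant kcal A / mol / e^2.
#' @param dielectric relative dielectric (> 0).
#' @param cutoff Angstrom, or `Inf` for all pairs.
#' @param switch_width Angstrom of the switching region below the cutoff.
#' @param scale14_lj,scale14_coul scale factors in `[0, 1]` for pairs
#'   separated by exactly three bonds.
#' @return object of class `energy_options`.
#' @export
energy_options <- function(coulomb_constant = 332.0636, dielectric = 1,
                           cutoff = Inf, switch_width = 1.5,
                           scale14_lj = 0.5, scale14_coul = 0.5) {
  stopifnot(dielectric > 0, scale14_lj >= 0, scale14_lj <= 1,
            scale14_coul >= 0, scale14_coul <= 1)
  structure(list(coulomb_constant = coulomb_constant,
                 dielectric = dielectric, cutoff = cutoff,
                 switch_width = switch_width,
                 scale14_lj = scale14_lj, scale14_coul = scale14_coul),
            class = "energy_options")
}

#' Read a force-field parameter table
#'
#' Parses the packaged plain-text format: `ATOM` records give per-atom type,
#' partial charge, Lennard-Jones sigma and epsilon keyed by (residue, atom
#' name); `BOND` records the intra-residue bonded topology; `FORMAL` the
#' residue formal charge; `TORSION` periodic cosine-series terms keyed by an
#' atom-type quadruple. The file hash is kept so runs can log the parameter
#' version.
#'
#' @param path table file; defaults to the packaged table.
#' @return list with `atoms`, `bonds`, `formal`, `torsions`, `version`,
#'   `hash`.
#' @export
read_forcefield <- function(path = system.file("extdata", "forcefield.tsv",
                                               package = "tcrdom")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  f <- strsplit(lines, "\t")
  kind <- vapply(f, `[[`, "", 1L)
  get <- function(k) f[kind == k]
  atoms <- do.call(rbind, lapply(get("ATOM"), function(r) {
    data.frame(res = r[2], name = r[3], type = r[4],
               charge = as.numeric(r[5]), sigma = as.numeric(r[6]),
               eps = as.numeric(r[7]), stringsAsFactors = FALSE)
  }))
  stopifnot(all(atoms$eps >= 0), all(atoms$sigma > 0))
  bonds <- do.call(rbind, lapply(get("BOND"), function(r) {
    data.frame(res = r[2], a = r[3], b = r[4], stringsAsFactors = FALSE)
  }))
  formal <- vapply(get("FORMAL"), function(r) as.numeric(r[3]), numeric(1))
  names(formal) <- vapply(get("FORMAL"), `[[`, "", 2L)
  torsions <- do.call(rbind, lapply(get("TORSION"), function(r) {
    data.frame(t1 = r[2], t2 = r[3], t3 = r[4], t4 = r[5],
               K = as.numeric(r[6]), n = as.integer(r[7]),
               phase = as.numeric(r[8]) * pi / 180, stringsAsFactors = FALSE)
  }))
  stopifnot(all(is.finite(torsions$K)))
  version <- vapply(get("VERSION"), `[[`, "", 2L)
  list(atoms = atoms, bonds = bonds, formal = formal, torsions = torsions,
       version = if (length(version)) version[1] else "unversioned",
       hash = unname(tools::md5sum(path)))
}

.tcrdom_cache <- new.env(parent = emptyenv())

#' Packaged default force field (cached)
#' @return see [read_forcefield()].
#' @export
default_forcefield <- function() {
  if (is.null(.tcrdom_cache$ff)) .tcrdom_cache$ff <- read_forcefield()
  .tcrdom_cache$ff
}

#' Assign force-field parameters to an assembly
#'
#' Attaches per-atom charge/sigma/epsilon/type, builds the bonded topology
#' (residue-template bonds plus peptide bonds between consecutive residues
#' of a chain) and precomputes the 1-2/1-3 exclusion and 1-4 pair sets.
#' Every residue must be a standard amino acid present in the table; the
#' per-residue net charge is checked against the table's formal charge.
#'
#' @param assembly a `tcr_assembly`.
#' @param ff a force field from [read_forcefield()].
#' @return a `parameterized_assembly` (subclass of `tcr_assembly` with
#'   `params`, `bonds`, `excl`, `pairs14`, `ff_hash`).
#' @export
assign_parameters <- function(assembly, ff = default_forcefield()) {
  at <- assembly$atoms
  key <- paste(at$resid, at$elety)
  ffkey <- paste(ff$atoms$res, ff$atoms$name)
  m <- match(key, ffkey)
  if (anyNA(m)) {
    off <- unique(key[is.na(m)])
    stop("parameterization error: no parameters for ",
         paste(off, collapse = "; "))
  }
  params <- ff$atoms[m, c("type", "charge", "sigma", "eps")]
  rownames(params) <- NULL

  res_key <- paste(at$unit, at$chain, at$resno, at$insert)
  for (rk in unique(res_key)) {
    rows <- which(res_key == rk)
    resid <- at$resid[rows[1]]
    want <- ff$formal[[resid]]
    if (!is.null(want) &&
        abs(sum(params$charge[rows]) - want) > 1e-6) {
      stop("parameterization error: net charge of ", rk, " (", resid,
           ") deviates from formal charge")
    }
  }

  bonds <- build_bonds(at, ff)
  sep <- bonded_separations(nrow(at), bonds)
  out <- assembly
  out$params <- params
  out$bonds <- bonds
  out$excl <- sep$excl
  out$pairs14 <- sep$pairs14
  out$ff_hash <- ff$hash
  out$torsions <- ff$torsions
  class(out) <- c("parameterized_assembly", class(assembly))
  out
}

build_bonds <- function(at, ff) {
  res_key <- paste(at$unit, at$chain, at$resno, at$insert)
  ures <- unique(res_key)
  bonds <- matrix(integer(), 0L, 2L)
  for (rk in ures) {
    rows <- which(res_key == rk)
    resid <- at$resid[rows[1]]
    tmpl <- ff$bonds[ff$bonds$res == resid, , drop = FALSE]
    ia <- rows[match(tmpl$a, at$elety[rows])]
    ib <- rows[match(tmpl$b, at$elety[rows])]
    ok <- !is.na(ia) & !is.na(ib)
    bonds <- rbind(bonds, cbind(ia[ok], ib[ok]))
  }
  # peptide bonds: C(i) - N(i+1) between consecutive residues of one chain
  for (u in unique(at$unit)) {
    for (ch in unique(at$chain[at$unit == u])) {
      rows <- which(at$unit == u & at$chain == ch)
      resnos <- sort(unique(at$resno[rows]))
      for (k in seq_len(length(resnos) - 1L)) {
        ci <- rows[at$elety[rows] == "C" & at$resno[rows] == resnos[k]]
        ni <- rows[at$elety[rows] == "N" & at$resno[rows] == resnos[k + 1L]]
        if (length(ci) == 1L && length(ni) == 1L) {
          d <- sqrt(sum((as.numeric(at[ci, c("x", "y", "z")]) -
                           as.numeric(at[ni, c("x", "y", "z")]))^2))
          if (d < 2.5) bonds <- rbind(bonds, c(ci, ni))
        }
      }
    }
  }
  bonds
}

# pair keys for fast exclusion lookups
pair_key <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * n + hi
}

bonded_separations <- function(n, bonds) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  excl <- integer()  # keys of 1-2 and 1-3 pairs
  p14 <- integer()   # keys of 1-4 pairs
  for (a in seq_len(n)) {
    d1 <- adj[[a]]
    d2 <- setdiff(unique(unlist(adj[d1])), c(a, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(a, d1, d2))
    if (length(d1) || length(d2)) {
      excl <- c(excl, pair_key(a, c(d1, d2), n))
    }
    if (length(d3)) p14 <- c(p14, pair_key(a, d3, n))
  }
  list(excl = unique(excl), pairs14 = unique(p14))
}

#' Precompute a nonbonded pair block
#'
#' Builds the pair list between two atom sets (or within one set when
#' `set_b` is `NULL`), drops 1-2/1-3 bonded pairs, applies 1-4 scaling, and
#' precomputes the Lennard-Jones `A = 4 eps sigma^12`, `B = 4 eps sigma^6`
#' and Coulomb prefactors so repeated evaluation during optimization is a
#' vectorized sum.
#'
#' @keywords internal
pair_block <- function(pa, set_a, set_b = NULL, opts = energy_options()) {
  n <- nrow(pa$atoms)
  if (is.null(set_b)) {
    if (length(set_a) < 2L) return(empty_block())
    cmb <- utils::combn(sort(set_a), 2L)
    i <- cmb[1L, ]; j <- cmb[2L, ]
  } else {
    g <- expand.grid(i = set_a, j = set_b)
    keep <- g$i != g$j
    # canonical (lo, hi) pairs in key order so the summation order -- and
    # hence the floating-point result -- is independent of argument order
    lo <- pmin(g$i[keep], g$j[keep]); hi <- pmax(g$i[keep], g$j[keep])
    ord <- order((lo - 1) * n + hi)
    i <- lo[ord]; j <- hi[ord]
  }
  if (!length(i)) return(empty_block())
  keys <- pair_key(i, j, n)
  drop <- keys %in% pa$excl
  i <- i[drop == FALSE]; j <- j[drop == FALSE]; keys <- keys[!drop]
  if (!length(i)) return(empty_block())
  s14 <- keys %in% pa$pairs14
  q <- pa$params$charge
  sg <- pa$params$sigma
  ep <- pa$params$eps
  sig <- sqrt(sg[i] * sg[j])        # geometric mean, OPLS convention
  eps <- sqrt(ep[i] * ep[j])
  lj_scale <- ifelse(s14, opts$scale14_lj, 1)
  cl_scale <- ifelse(s14, opts$scale14_coul, 1)
  A <- 4 * eps * sig^12 * lj_scale
  B <- 4 * eps * sig^6 * lj_scale
  C <- opts$coulomb_constant / opts$dielectric * q[i] * q[j] * cl_scale
  list(i = i, j = j, A = A, B = B, C = C, n = length(i))
}

empty_block <- function() list(i = integer(), j = integer(), A = numeric(),
                               B = numeric(), C = numeric(), n = 0L)

merge_blocks <- function(...) {
  bl <- list(...)
  list(i = unlist(lapply(bl, `[[`, "i")),
       j = unlist(lapply(bl, `[[`, "j")),
       A = unlist(lapply(bl, `[[`, "A")),
       B = unlist(lapply(bl, `[[`, "B")),
       C = unlist(lapply(bl, `[[`, "C")),
       n = sum(vapply(bl, `[[`, 0L, "n")))
}

switch_factors <- function(r, opts) {
  # smooth C1 switch from 1 at r_on to 0 at cutoff
  if (!is.finite(opts$cutoff)) return(NULL)
  r_on <- opts$cutoff - opts$switch_width
  s <- rep(1, length(r)); ds <- rep(0, length(r))
  inside <- r > r_on & r < opts$cutoff
  t <- (r[inside] - r_on) / opts$switch_width
  s[inside] <- 1 - t^2 * (3 - 2 * t)
  ds[inside] <- -6 * t * (1 - t) / opts$switch_width
  s[r >= opts$cutoff] <- 0
  list(s = s, ds = ds)
}

block_energy <- function(xyz, block, opts) {
  if (!block$n) return(0)
  dx <- xyz[block$i, , drop = FALSE] - xyz[block$j, , drop = FALSE]
  d2 <- rowSums(dx * dx)
  inv6 <- 1 / d2^3
  r <- sqrt(d2)
  e <- block$A * inv6 * inv6 - block$B * inv6 + block$C / r
  sw <- switch_factors(r, opts)
  if (!is.null(sw)) e <- e * sw$s
  sum(e)
}

# energy plus dense per-atom gradient (n_atoms x 3)
block_energy_gradient <- function(xyz, block, opts, grad = NULL) {
  if (is.null(grad)) grad <- matrix(0, nrow(xyz), 3L)
  if (!block$n) return(list(energy = 0, gradient = grad))
  dx <- xyz[block$i, , drop = FALSE] - xyz[block$j, , drop = FALSE]
  d2 <- rowSums(dx * dx)
  inv2 <- 1 / d2
  inv6 <- inv2 * inv2 * inv2
  r <- sqrt(d2)
  e <- block$A * inv6 * inv6 - block$B * inv6 + block$C / r
  # dE/dr / r  (per pair)
  g_over_r <- (-12 * block$A * inv6 * inv6 + 6 * block$B * inv6 -
                 block$C / r) * inv2
  sw <- switch_factors(r, opts)
  if (!is.null(sw)) {
    g_over_r <- g_over_r * sw$s + e * sw$ds / r
    e <- e * sw$s
  }
  gp <- dx * g_over_r
  idx <- c(block$i, block$j)
  contrib <- rbind(gp, -gp)
  acc <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(acc))
  grad[rows, ] <- grad[rows, ] + acc
  list(energy = sum(e), gradient = grad)
}

#' Nonbonded interaction energy between (or within) atom groups
#'
#' Sum of 12-6 Lennard-Jones and Coulomb terms over the in-scope pairs.
#' Within one group, 1-2 and 1-3 bonded pairs are excluded and 1-4 pairs
#' scaled; across two groups all pairs count (no bonds cross units).
#' Symmetric in its arguments.
#'
#' @param pa a `parameterized_assembly`.
#' @param group_a,group_b integer atom-index vectors; omit `group_b` (or
#'   pass the same set) for an intra-group energy.
#' @param opts an [energy_options()].
#' @return energy in kcal/mol.
#' @export
nonbonded_energy <- function(pa, group_a, group_b = NULL,
                             opts = energy_options()) {
  if (!inherits(pa, "parameterized_assembly")) {
    stop("assembly is not parameterized; call assign_parameters() first")
  }
  if (!is.null(group_b) && setequal(group_a, group_b)) group_b <- NULL
  block <- pair_block(pa, group_a, group_b, opts)
  block_energy(assembly_xyz(pa), block, opts)
}

# ---- dihedrals and side-chain torsion terms ----

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return angle in radians, in (-pi, pi].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossprod3(b1, b2)
  n2 <- crossprod3(b2, b3)
  m1 <- crossprod3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

carboxamide_axis <- function(pa, chain, resno, insert = "") {
  rows <- residue_rows(pa, chain, resno, insert)
  if (!length(rows)) stop("residue ", chain, ":", resno, " not found")
  resid <- pa$atoms$resid[rows[1]]
  nm <- amide_atom_names(resid)
  idx <- function(name) {
    r <- rows[match(name, pa$atoms$elety[rows])]
    if (is.na(r)) stop("incomplete residue ", chain, ":", resno,
                       ": missing atom ", name)
    r
  }
  moved <- rows[pa$atoms$elety[rows] %in% c(nm$o, nm$n, nm$h)]
  list(resid = resid, rows = rows,
       b_prox = idx(nm$cprox), b_dist = idx(nm$c),
       moved = moved, unit = pa$atoms$unit[rows[1]])
}

# torsion terms whose dihedral tracks the carboxamide rotation 1:1:
# central bond = rotation axis, fourth atom in the moved set
axis_torsion_terms <- function(pa, ax) {
  adj_of <- function(a) {
    b <- pa$bonds
    c(b[b[, 1] == a, 2], b[b[, 2] == a, 1])
  }
  starts <- setdiff(adj_of(ax$b_prox), c(ax$b_dist, ax$moved))
  ends <- intersect(adj_of(ax$b_dist), ax$moved)
  terms <- list()
  types <- pa$params$type
  tors <- pa$torsions
  for (a in starts) {
    for (d in ends) {
      quad <- c(types[a], types[ax$b_prox], types[ax$b_dist], types[d])
      hit <- which((tors$t1 == quad[1] & tors$t2 == quad[2] &
                      tors$t3 == quad[3] & tors$t4 == quad[4]) |
                     (tors$t4 == quad[1] & tors$t3 == quad[2] &
                        tors$t2 == quad[3] & tors$t1 == quad[4]))
      for (h in hit) {
        terms[[length(terms) + 1L]] <-
          list(atoms = c(a, ax$b_prox, ax$b_dist, d),
               K = tors$K[h], n = tors$n[h], phase = tors$phase[h])
      }
    }
  }
  terms
}

torsion_terms_energy <- function(xyz, terms, dphi = 0) {
  e <- 0; de <- 0
  for (t in terms) {
    p <- lapply(t$atoms, function(k) xyz[k, ])
    phi <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]) + dphi
    e <- e + t$K * (1 + cos(t$n * phi - t$phase))
    de <- de - t$K * t$n * sin(t$n * phi - t$phase)
  }
  list(energy = e, denergy = de)
}

#' Bonded side-chain energy of a carboxamide dihedral
#'
#' Cosine-series torsion energy of the dihedral that rotates an Asn/Gln
#' carboxamide group (axis Cbeta-Cgamma for Asn, Cgamma-Cdelta for Gln),
#' evaluated at the current coordinates optionally offset by
#' `delta_angle`. Side-chain terms invariant under this rotation (bonds,
#' angles, dihedrals not spanning the axis) are constant along the sampled
#' coordinate and omitted.
#'
#' @param pa a `parameterized_assembly`.
#' @param chain,resno,insert residue selector; must be Asn or Gln.
#' @param delta_angle offset added to the current dihedral, radians.
#' @return energy in kcal/mol.
#' @export
sidechain_bonded_energy <- function(pa, chain, resno, insert = "",
                                    delta_angle = 0) {
  ax <- carboxamide_axis(pa, chain, resno, insert)
  terms <- axis_torsion_terms(pa, ax)
  torsion_terms_energy(assembly_xyz(pa), terms, dphi = delta_angle)$energy
}

all_unit_pairs <- function(labels) {
  if (length(labels) < 2L) return(list())
  cmb <- utils::combn(labels, 2L, simplify = FALSE)
  cmb
}

unit_internal_energy <- function(pa, label, opts) {
  idx <- unit_indices(pa, label)
  e <- nonbonded_energy(pa, idx, opts = opts)
  qres <- unique(pa$atoms[idx, c("chain", "resno", "insert", "resid")])
  qres <- qres[qres$resid %in% c("ASN", "GLN"), , drop = FALSE]
  for (k in seq_len(nrow(qres))) {
    e <- e + tryCatch(
      sidechain_bonded_energy(pa, qres$chain[k], qres$resno[k],
                              qres$insert[k]),
      error = function(e2) 0)  # residues without placed amide H contribute 0
  }
  e
}

#' Binding energy of an assembly
#'
#' `E_bind = E_complex - (E_alpha + E_beta + E_mu)`, where the unit energies
#' are those of the isolated rigid units. Because intra-unit terms are
#' constant under rigid motion, the binding energy reduces to the sum of
#' inter-unit nonbonded energies plus any intra-unit terms altered by the
#' sampled carboxamide side chains. Unit energies are constant over a
#' prediction run and can be supplied precomputed via `reference_units`.
#'
#' @param pa a `parameterized_assembly` (2 or 3 units).
#' @param opts an [energy_options()].
#' @param reference_units optional named numeric vector of cached unit
#'   energies (`VA`, `VB`, `PMHC`), e.g. computed once at the start of a run.
#' @return an `energy_report`: list with `E_complex`, `E_alpha`, `E_beta`,
#'   `E_mu` (`NA` for 2-unit assemblies) and `E_bind`, kcal/mol.
#' @export
binding_energy <- function(pa, opts = energy_options(),
                           reference_units = NULL) {
  labels <- unit_labels(pa)
  e_unit <- vapply(labels, function(u) unit_internal_energy(pa, u, opts),
                   numeric(1))
  if (!is.null(reference_units)) {
    stopifnot(all(labels %in% names(reference_units)))
    e_ref <- reference_units[labels]
  } else {
    e_ref <- e_unit
  }
  xyz <- assembly_xyz(pa)
  inter <- 0
  for (pr in all_unit_pairs(labels)) {
    block <- pair_block(pa, unit_indices(pa, pr[1]), unit_indices(pa, pr[2]),
                        opts)
    inter <- inter + block_energy(xyz, block, opts)
  }
  e_complex <- sum(e_unit) + inter
  structure(list(E_complex = e_complex,
                 E_alpha = unname(e_ref["VA"]),
                 E_beta = unname(e_ref["VB"]),
                 E_mu = if ("PMHC" %in% labels) unname(e_ref["PMHC"]) else NA_real_,
                 E_bind = e_complex - sum(e_ref)),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("E_complex = %.4f  E_alpha = %.4f  E_beta = %.4f  E_mu = %s\n",
              x$E_complex, x$E_alpha, x$E_beta,
              ifelse(is.na(x$E_mu), "-", sprintf("%.4f", x$E_mu))))
  cat(sprintf("E_bind    = %.4f kcal/mol\n", x$E_bind))
  invisible(x)
}
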