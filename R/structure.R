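#' @importFrom stats setNames
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

UNIT_LABELS <- c("VA", "VB", "PMHC")

element_from_name <- function(elety) {
  # PDB convention: hydrogens may be named like HB2 or 1HB2/HE21; other
  # protein atoms start with their element letter
  nm <- toupper(trimws(elety))
  first <- substr(gsub("^[0-9]", "", nm), 1L, 1L)
  ifelse(first %in% c("H", "C", "N", "O", "S"), first, first)
}

empty_atoms_df <- function() {
  data.frame(unit = character(), chain = character(), resno = integer(),
             insert = character(), resid = character(), elety = character(),
             elesy = character(), x = numeric(), y = numeric(), z = numeric(),
             o = numeric(), b = numeric(), stringsAsFactors = FALSE)
}

#' Construct an assembly of modeled units
#'
#' An assembly holds the atoms of two or three structural units: the TCR
#' variable domains `VA` and `VB`, and optionally a class-I `PMHC` unit
#' (alpha1/alpha2 platform plus peptide). Atoms are stored unit-contiguous
#' in the fixed order VA, VB, PMHC.
#'
#' @param atoms data frame with columns `unit, chain, resno, insert, resid,
#'   elety, elesy, x, y, z, o, b` (coordinates in Angstrom, author residue
#'   numbering).
#' @param meta named list of metadata (source id, biological-unit index,
#'   peptide chain id, pMHC translation axis, ...).
#' @return object of class `tcr_assembly`.
#' @export
new_assembly <- function(atoms, meta = list()) {
  stopifnot(is.data.frame(atoms))
  atoms$unit <- as.character(atoms$unit)
  bad <- setdiff(unique(atoms$unit), UNIT_LABELS)
  if (length(bad)) stop("unknown unit label(s): ", paste(bad, collapse = ", "))
  if (!all(c("VA", "VB") %in% atoms$unit)) {
    stop("an assembly must contain VA and VB units")
  }
  # enforce unit-contiguous storage in canonical order
  ord <- order(match(atoms$unit, UNIT_LABELS))
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in assembly")
  }
  structure(list(atoms = atoms, meta = meta), class = "tcr_assembly")
}

#' @export
print.tcr_assembly <- function(x, ...) {
  tab <- table(x$atoms$unit)
  cat("tcr_assembly:", nrow(x$atoms), "atoms;",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' Atom indices of one unit
#' @param assembly a `tcr_assembly`.
#' @param label `"VA"`, `"VB"` or `"PMHC"`.
#' @return integer vector of row indices into `assembly$atoms`.
#' @export
unit_indices <- function(assembly, label) {
  which(assembly$atoms$unit == label)
}

#' Unit labels present in an assembly
#' @param assembly a `tcr_assembly`.
#' @export
unit_labels <- function(assembly) {
  intersect(UNIT_LABELS, unique(assembly$atoms$unit))
}

#' Coordinate matrix of an assembly
#' @param assembly a `tcr_assembly`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
assembly_xyz <- function(assembly) {
  as.matrix(assembly$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of an assembly
#' @param assembly a `tcr_assembly`.
#' @param xyz n x 3 matrix matching the atom count.
#' @export
set_assembly_xyz <- function(assembly, xyz) {
  stopifnot(nrow(xyz) == nrow(assembly$atoms), ncol(xyz) == 3L)
  assembly$atoms$x <- xyz[, 1]
  assembly$atoms$y <- xyz[, 2]
  assembly$atoms$z <- xyz[, 3]
  assembly
}

#' Read a protein structure from a PDB file
#'
#' Loads all ATOM/HETATM records with author numbering and insertion codes
#' preserved. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by the alphabetically first altloc code).
#'
#' @param path PDB file.
#' @param bio_unit MODEL number to read when the file holds several models.
#' @return a `tcr_system`: list with an `atoms` data frame (not yet split
#'   into units) and `meta`. Use [extract_modeling_units()] to obtain an
#'   assembly.
#' @export
read_structure <- function(path, bio_unit = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("PDB format error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (!is.null(at$alt)) {
    keep <- rep(TRUE, nrow(at))
    alt <- at$alt
    alt[is.na(alt)] <- ""
    has_alt <- alt != ""
    if (any(has_alt)) {
      key <- paste(at$chain, at$resno, at$insert, at$elety)
      for (k in unique(key[has_alt])) {
        idx <- which(key == k)
        if (length(idx) > 1L) {
          occ <- at$o[idx]
          occ[is.na(occ)] <- 0
          best <- idx[order(-occ, alt[idx])][1L]
          keep[setdiff(idx, best)] <- FALSE
        }
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  insert <- at$insert
  insert[is.na(insert)] <- ""
  atoms <- data.frame(unit = NA_character_,
                      chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      insert = as.character(insert),
                      resid = toupper(as.character(at$resid)),
                      elety = as.character(at$elety),
                      elesy = element_from_name(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      record = as.character(at$type),
                      stringsAsFactors = FALSE)
  if (!any(atoms$resid %in% STANDARD_AA)) {
    stop("no protein content in ", path)
  }
  structure(list(atoms = atoms,
                 meta = list(source = basename(path), bio_unit = bio_unit)),
            class = "tcr_system")
}

#' Read a unit-map configuration
#'
#' Plain-text map of structural units to chain/residue ranges, one entry per
#' line: `UNIT chain first_resno last_resno [peptide]`. A `PMHC` unit may
#' list several entries (platform chain and peptide chain); the peptide
#' chain is tagged with the literal word `peptide`.
#'
#' @param path text file; `#` starts a comment.
#' @return named list of entry lists usable by [extract_modeling_units()].
#' @export
read_unit_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 2L) stop("bad unit-map line: ", ln)
    unit <- toupper(f[1])
    if (!unit %in% UNIT_LABELS) stop("unknown unit in map: ", unit)
    entry <- list(chain = f[2])
    if (length(f) >= 4L) entry$resno <- c(as.integer(f[3]), as.integer(f[4]))
    entry$peptide <- any(tolower(f) == "peptide")
    out[[unit]] <- c(out[[unit]], list(entry))
  }
  out
}

normalize_map_entries <- function(entries) {
  if (!is.null(entries$chain)) entries <- list(entries)
  entries
}

#' Extract the modeled units from a full system
#'
#' Keeps only the residues mapped to the VA, VB and (optionally) PMHC
#' units; everything else -- constant domains, the MHC alpha3 domain,
#' beta2-microglobulin and all non-protein atoms -- is discarded.
#' Coordinates of retained atoms are untouched.
#'
#' @param system a `tcr_system` from [read_structure()], or a
#'   `tcr_assembly` (re-mapping).
#' @param chain_map named list (`VA`, `VB`, optionally `PMHC`); each element
#'   is one entry `list(chain =, resno = c(first, last), peptide =)` or a
#'   list of such entries. See [read_unit_map()].
#' @return a [new_assembly()] with 2 or 3 units.
#' @export
extract_modeling_units <- function(system, chain_map) {
  if (!all(c("VA", "VB") %in% names(chain_map))) {
    stop("mapping error: chain_map must name VA and VB")
  }
  at <- system$atoms
  peptide_chain <- NULL
  picked <- list()
  for (unit in intersect(UNIT_LABELS, names(chain_map))) {
    rows <- integer()
    for (entry in normalize_map_entries(chain_map[[unit]])) {
      sel <- at$chain == entry$chain & at$resid %in% STANDARD_AA
      if (!any(at$chain == entry$chain)) {
        stop("mapping error: chain '", entry$chain, "' absent from structure")
      }
      if (!is.null(entry$resno)) {
        sel <- sel & at$resno >= entry$resno[1] & at$resno <= entry$resno[2]
      }
      if (isTRUE(entry$peptide)) peptide_chain <- entry$chain
      rows <- c(rows, which(sel))
    }
    if (!length(rows)) {
      stop("mapping error: zero residues mapped to unit ", unit)
    }
    picked[[unit]] <- sort(unique(rows))
  }
  atoms <- do.call(rbind, lapply(names(picked), function(u) {
    df <- at[picked[[u]], , drop = FALSE]
    df$unit <- u
    df
  }))
  atoms$record <- NULL
  meta <- system$meta
  meta$peptide_chain <- peptide_chain
  new_assembly(atoms, meta = meta)
}

amide_atom_names <- function(resid) {
  switch(resid,
         ASN = list(cprox = "CB", c = "CG", o = "OD1", n = "ND2",
                    h = c("HD21", "HD22")),
         GLN = list(cprox = "CG", c = "CD", o = "OE1", n = "NE2",
                    h = c("HE21", "HE22")),
         stop("unsupported residue for carboxamide operations: ", resid))
}

residue_rows <- function(assembly, chain, resno, insert = "") {
  which(assembly$atoms$chain == chain & assembly$atoms$resno == resno &
          assembly$atoms$insert == insert)
}

#' Place (or re-place) the amide hydrogens of an Asn/Gln residue
#'
#' The two hydrogens are placed on the terminal amide nitrogen, trigonal
#' planar (120 degrees) in the carboxamide plane, with an N-H bond length of
#' 1.01 Angstrom. Heavy atoms are untouched; existing amide hydrogens are
#' replaced, so the operation is idempotent. The hydrogen anti to the
#' carbonyl oxygen gets the `21` name.
#'
#' @param assembly a `tcr_assembly`.
#' @param chain,resno,insert residue selector (author numbering).
#' @return the updated assembly.
#' @export
place_amide_hydrogens <- function(assembly, chain, resno, insert = "") {
  rows <- residue_rows(assembly, chain, resno, insert)
  if (!length(rows)) stop("residue ", chain, ":", resno, " not found")
  res <- assembly$atoms[rows, , drop = FALSE]
  resid <- res$resid[1]
  nm <- amide_atom_names(resid)
  need <- c(nm$cprox, nm$c, nm$o, nm$n)
  if (!all(need %in% res$elety)) {
    stop("incomplete residue ", chain, ":", resno,
         ": missing carboxamide heavy atom(s) ",
         paste(setdiff(need, res$elety), collapse = ","))
  }
  p <- function(name) as.numeric(res[match(name, res$elety), c("x", "y", "z")])
  C <- p(nm$c); O <- p(nm$o); N <- p(nm$n)
  normal <- crossprod3(O - C, N - C)
  normal <- normal / sqrt(sum(normal^2))
  d0 <- (C - N) / sqrt(sum((C - N)^2))
  hpos <- lapply(c(2 * pi / 3, -2 * pi / 3), function(ang) {
    R <- rotation_from_vector(ang * normal)
    N + 1.01 * as.numeric(R %*% d0)
  })
  # anti (farther from O) hydrogen is *21
  d_o <- vapply(hpos, function(h) sum((h - O)^2), numeric(1))
  hpos <- hpos[order(-d_o)]

  keep <- rows[!(res$elety %in% nm$h)]
  n_row <- rows[match(nm$n, res$elety)]
  template <- assembly$atoms[n_row, , drop = FALSE]
  hdf <- do.call(rbind, lapply(1:2, function(k) {
    r <- template
    r$elety <- nm$h[k]
    r$elesy <- "H"
    r$x <- hpos[[k]][1]; r$y <- hpos[[k]][2]; r$z <- hpos[[k]][3]
    r$o <- 1; r$b <- 0
    r
  }))
  before <- assembly$atoms[seq_len(nrow(assembly$atoms)) <= max(keep) &
                             !(seq_len(nrow(assembly$atoms)) %in%
                                 setdiff(rows, keep)), , drop = FALSE]
  after_idx <- setdiff(seq_len(nrow(assembly$atoms)),
                       c(seq_len(max(keep)), rows))
  atoms <- rbind(before, hdf, assembly$atoms[after_idx, , drop = FALSE])
  rownames(atoms) <- NULL
  assembly$atoms <- atoms
  assembly
}

#' Write an assembly to a PDB file
#'
#' Chains are emitted in unit order VA, VB, PMHC. Round-tripping through
#' [read_structure()] reproduces coordinates to PDB precision (1e-3 A).
#'
#' @param assembly a `tcr_assembly`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(assembly, path) {
  at <- assembly$atoms
  if (!nrow(at)) stop("cannot write an empty assembly")
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, resid = at$resid, chain = at$chain,
                     insert = ifelse(at$insert == "", NA, at$insert),
                     elety = at$elety, o = at$o, b = at$b,
                     elesy = at$elesy)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' All-atom coordinates of one residue
#' @keywords internal
residue_xyz <- function(assembly, chain, resno, insert = "") {
  rows <- residue_rows(assembly, chain, resno, insert)
  as.matrix(assembly$atoms[rows, c("x", "y", "z")])
}
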