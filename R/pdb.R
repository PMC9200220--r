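# PDB parsing and binding-pocket extraction. The pocket is defined exactly
# as the screening method requires: every protein residue with any atom
# within a distance cutoff (default 10 A = 1 nm) of any atom of a reference
# bound ligand, kept as a whole residue.

.DEFAULT_HET_EXCLUDE <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "ZN",
                          "CA", "MN", "SO4", "PO4", "GOL", "EDO")

.substr_trim <- function(line, a, b) trimws(substr(line, a, b))

# Guess the element from the PDB atom-name field when columns 77-78 are
# absent; two-letter elements (Cl, Br) are only taken from the element field.
.element_from_name <- function(name) {
  sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
}

#' Parse PDB text into a structure
#'
#' Reads fixed-column `ATOM`/`HETATM` records. `ATOM` records populate the
#' protein; non-water, non-buffer `HETATM` records populate `het_groups`,
#' keyed `"RES:CHAIN:NUM"`. Only the first `MODEL` of a multi-model file is
#' read. Alternate locations keep the highest-occupancy conformer (ties:
#' altloc letter order).
#'
#' @param pdb_text a character scalar (whole file) or vector of lines.
#' @param het_exclude residue names never treated as reference ligands
#'   (waters and common buffer components by default).
#' @return object of class `pdb_structure`: list with `atoms` (data frame:
#'   serial, name, altloc, resname, chain, resno, icode, x, y, z, occupancy,
#'   element, het) and `het_groups` (named list of atom row indices).
#' @export
parse_structure <- function(pdb_text, het_exclude = .DEFAULT_HET_EXCLUDE) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1L]]
  } else pdb_text
  rec <- substr(lines, 1L, 6L)
  first_end <- which(trimws(rec) == "ENDMDL")[1L]
  if (!is.na(first_end)) lines <- lines[seq_len(first_end)]
  keep <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  if (!length(keep)) stop("empty-structure error: no ATOM/HETATM records")
  n <- length(keep)
  atoms <- data.frame(
    serial = integer(n), name = character(n), altloc = character(n),
    resname = character(n), chain = character(n), resno = integer(n),
    icode = character(n), x = numeric(n), y = numeric(n), z = numeric(n),
    occupancy = numeric(n), element = character(n), het = logical(n),
    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    ln <- lines[keep[k]]
    if (nchar(ln) < 54L) {
      stop(sprintf("malformed PDB record at line %d: too short (%d chars)",
                   keep[k], nchar(ln)))
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz) || !all(is.finite(xyz))) {
      stop(sprintf("malformed PDB record at line %d: bad coordinates",
                   keep[k]))
    }
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    el <- .substr_trim(ln, 77, 78)
    nm <- .substr_trim(ln, 13, 16)
    if (!nzchar(el)) el <- .element_from_name(nm)
    atoms[k, ] <- list(
      serial = suppressWarnings(as.integer(.substr_trim(ln, 7, 11))),
      name = nm, altloc = .substr_trim(ln, 17, 17),
      resname = .substr_trim(ln, 18, 20),
      chain = .substr_trim(ln, 22, 22),
      resno = suppressWarnings(as.integer(.substr_trim(ln, 23, 26))),
      icode = .substr_trim(ln, 27, 27),
      x = xyz[1L], y = xyz[2L], z = xyz[3L],
      occupancy = if (is.na(occ)) 1 else occ,
      element = paste0(toupper(substr(el, 1, 1)),
                       tolower(substr(el, 2, 2))),
      het = startsWith(lines[keep[k]], "HETATM"))
  }
  # altloc resolution: within (chain, resno, icode, name) keep the highest
  # occupancy record, ties by altloc letter order
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, atoms$het)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord[!duplicated(key[ord])], , drop = FALSE]
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL

  hets <- which(atoms$het & !atoms$resname %in% het_exclude)
  het_groups <- split(hets, paste(atoms$resname[hets], atoms$chain[hets],
                                  atoms$resno[hets], sep = ":"))
  structure(list(atoms = atoms, het_groups = het_groups),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure: %d protein atoms, %d het group(s)%s>\n",
              sum(!x$atoms$het), length(x$het_groups),
              if (length(x$het_groups))
                paste0(" [", paste(names(x$het_groups), collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Pocket definition settings
#' @param radius distance cutoff in Angstrom (default 10 = 1 nm).
#' @param selection_unit `"residue"` (whole residues kept, default) or
#'   `"atom"`.
#' @return a `pocket_config`.
#' @export
pocket_config <- function(radius = 10, selection_unit = c("residue", "atom")) {
  stopifnot(radius > 0)
  structure(list(radius = radius,
                 selection_unit = match.arg(selection_unit)),
            class = "pocket_config")
}

#' Extract the binding pocket around a reference ligand
#'
#' A protein residue belongs to the pocket iff the minimum Euclidean
#' distance over all (residue atom, ligand atom) pairs is at most
#' `cfg$radius`; included residues keep all their atoms. An empty pocket is
#' a warning, not an error.
#'
#' @param s a `pdb_structure`.
#' @param ligand_id a key of `s$het_groups` (`"RES:CHAIN:NUM"`).
#' @param cfg a [pocket_config()].
#' @return object of class `pocket_structure`: list with `residues`
#'   (data frame chain/resno/icode/resname/min_dist), `atoms` (their atom
#'   records), `source` (ligand id).
#' @export
extract_pocket <- function(s, ligand_id, cfg = pocket_config()) {
  stopifnot(inherits(s, "pdb_structure"))
  if (!ligand_id %in% names(s$het_groups)) {
    stop(sprintf("unknown ligand id '%s'; available: %s", ligand_id,
                 paste(names(s$het_groups), collapse = ", ")))
  }
  lig <- s$atoms[s$het_groups[[ligand_id]], , drop = FALSE]
  stopifnot(nrow(lig) >= 1L)
  prot <- s$atoms[!s$atoms$het, , drop = FALSE]
  if (!nrow(prot)) {
    warning("structure has no protein atoms; pocket is empty")
  }
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # min distance from each protein atom to any ligand atom
  mind <- rep(Inf, nrow(prot))
  for (j in seq_len(nrow(lxyz))) {
    d <- sqrt((pxyz[, 1L] - lxyz[j, 1L])^2 + (pxyz[, 2L] - lxyz[j, 2L])^2 +
                (pxyz[, 3L] - lxyz[j, 3L])^2)
    mind <- pmin(mind, d)
  }
  if (cfg$selection_unit == "atom") {
    sel <- mind <= cfg$radius
    atoms <- prot[sel, , drop = FALSE]
    res <- unique(atoms[, c("chain", "resno", "icode", "resname")])
  } else {
    rkey <- paste(prot$chain, prot$resno, prot$icode, sep = ":")
    res_min <- tapply(mind, rkey, min)
    keep_res <- names(res_min)[res_min <= cfg$radius]
    sel <- rkey %in% keep_res
    atoms <- prot[sel, , drop = FALSE]
    res <- unique(data.frame(
      chain = prot$chain, resno = prot$resno, icode = prot$icode,
      resname = prot$resname, stringsAsFactors = FALSE)[sel, , drop = FALSE])
    res$min_dist <- as.numeric(res_min[paste(res$chain, res$resno, res$icode,
                                             sep = ":")])
  }
  if (!nrow(atoms)) {
    warning(sprintf("pocket around %s at radius %.2f A is empty",
                    ligand_id, cfg$radius))
  }
  rownames(atoms) <- NULL; rownames(res) <- NULL
  structure(list(residues = res, atoms = atoms, source = ligand_id,
                 radius = cfg$radius),
            class = "pocket_structure")
}

#' @export
print.pocket_structure <- function(x, ...) {
  cat(sprintf("<pocket_structure around %s: %d residues, %d atoms (r = %g A)>\n",
              x$source, nrow(x$residues), nrow(x$atoms), x$radius))
  invisible(x)
}

# Covalent radii (A) for bond perception on pocket heavy atoms.
.COV_RADII <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06, B = 0.82,
                F = 0.71, Cl = 0.99, Br = 1.14, I = 1.33)

#' Convert a pocket into a featurizable pseudo-molecule
#'
#' Heavy pocket atoms become graph vertices; bonds are inferred by the
#' covalent-radius criterion `d <= r_i + r_j + 0.45 A`. The result is a
#' single, possibly disconnected `mol_graph` (one component per spatially
#' separate residue cluster) and is deterministic for fixed input.
#'
#' @param p a `pocket_structure`.
#' @param bond_slack additive slack of the distance criterion, in Angstrom.
#' @return a `mol_graph`.
#' @export
pocket_to_molecule <- function(p, bond_slack = 0.45) {
  stopifnot(inherits(p, "pocket_structure"))
  atoms <- p$atoms[!p$atoms$element %in% c("H", "D"), , drop = FALSE]
  if (!nrow(atoms)) stop("pocket has no heavy atoms")
  unknown <- !atoms$element %in% names(.COV_RADII)
  if (any(unknown)) {
    k <- which(unknown)[1L]
    stop(sprintf("unrecognized element '%s' for pocket atom %s %s%d",
                 atoms$element[k], atoms$name[k], atoms$chain[k],
                 atoms$resno[k]))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .COV_RADII[atoms$element]
  n <- nrow(atoms)
  bi <- integer(0); bj <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- sqrt(colSums((t(xyz[(i + 1L):n, , drop = FALSE]) - xyz[i, ])^2))
      cut <- r[i] + r[(i + 1L):n] + bond_slack
      hit <- which(d <= cut)
      if (length(hit)) {
        bi <- c(bi, rep(i, length(hit)))
        bj <- c(bj, i + hit)
      }
    }
  }
  mol_graph(atoms$element,
            bonds = data.frame(i = bi, j = bj, order = rep(1, length(bi))),
            source_id = paste0("pocket:", p$source))
}

#' Featurize a pocket as a 300-d vector
#'
#' Composition `pocket_to_molecule` -> `mol_to_sentence` ->
#' `embed_molecule`; the pocket half of the classifier input.
#'
#' @param p a `pocket_structure`.
#' @param table an `embedding_table`.
#' @param radii sentence radii.
#' @return a `feature_vector` of length `table$dim`.
#' @export
featurize_pocket <- function(p, table, radii = c(0L, 1L)) {
  embed_molecule(mol_to_sentence(pocket_to_molecule(p), radii), table)
}
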