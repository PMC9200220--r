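#' @useDynLib dfscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom quantile hclust cutree as.dist
#' @importFrom utils read.table write.table head tail
NULL

# Element data for the organic subset handled by the SMILES parser.
.ELEMENTS <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  z      = c(1L, 5L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L),
  mass   = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
             30.974, 32.06, 35.45, 79.904, 126.904),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

# Default valence sets; implicit hydrogens fill up to the smallest valence
# that accommodates the explicit bond order sum.
.VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, F = 1,
  P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

#' Construct a molecular graph
#'
#' The package-internal molecule container: a flat atom table plus a bond
#' table. Aromatic bonds carry order 1.5; hydrogens are implicit (counted per
#' heavy atom, never vertices).
#'
#' @param element character vector of element symbols (heavy atoms only).
#' @param bonds data frame with integer columns `i`, `j` (1-based atom
#'   indices) and numeric `order` (1, 2, 3 or 1.5 for aromatic).
#' @param aromatic logical vector, one flag per atom.
#' @param charge integer formal charges.
#' @param hcount integer total hydrogen count per atom, or `NA` to fill
#'   implicitly from default valences.
#' @param source_id identifier carried through featurization.
#' @return an object of class `mol_graph`.
#' @export
mol_graph <- function(element, bonds = NULL, aromatic = NULL, charge = NULL,
                      hcount = NULL, source_id = NA_character_) {
  n <- length(element)
  if (n < 1L) stop("mol_graph needs at least one heavy atom")
  bad <- !element %in% .ELEMENTS$symbol | element == "H"
  if (any(bad)) {
    stop(sprintf("unsupported element '%s' at atom %d",
                 element[which(bad)[1L]], which(bad)[1L]))
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  }
  if (is.null(aromatic)) aromatic <- rep(FALSE, n)
  if (is.null(charge)) charge <- rep(0L, n)
  if (is.null(hcount)) hcount <- rep(NA_integer_, n)
  stopifnot(nrow(bonds) == 0L ||
              (all(bonds$i >= 1L & bonds$i <= n & bonds$j >= 1L & bonds$j <= n)))
  mol <- structure(
    list(element = as.character(element), aromatic = as.logical(aromatic),
         charge = as.integer(charge), hcount = as.integer(hcount),
         bonds = bonds, source_id = source_id),
    class = "mol_graph")
  mol$hcount <- .fill_implicit_h(mol)
  mol
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph %s: %d heavy atoms, %d bonds, formula %s>\n",
              if (is.na(x$source_id)) "" else x$source_id,
              length(x$element), nrow(x$bonds), mol_formula(x)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$element)

# Sum of bond orders incident to each atom; aromatic bonds count 1 each and
# an aromatic atom is charged one extra unit for the delocalized pi bond.
.bond_order_used <- function(mol) {
  n <- n_atoms(mol)
  used <- numeric(n)
  b <- mol$bonds
  if (nrow(b)) {
    ord <- ifelse(b$order == 1.5, 1, b$order)
    for (k in seq_len(nrow(b))) {
      used[b$i[k]] <- used[b$i[k]] + ord[k]
      used[b$j[k]] <- used[b$j[k]] + ord[k]
    }
  }
  used + ifelse(mol$aromatic, 1, 0)
}

.fill_implicit_h <- function(mol) {
  used <- .bond_order_used(mol)
  h <- mol$hcount
  for (a in seq_along(h)) {
    if (!is.na(h[a])) next
    vals <- .VALENCES[[mol$element[a]]]
    v <- vals[vals >= used[a]][1L]
    h[a] <- if (is.na(v)) 0L else as.integer(max(0, v - used[a] - abs(mol$charge[a]) * 0))
  }
  # charged atoms: one fewer H per negative charge, one more per positive on N
  adj <- ifelse(mol$charge > 0 & mol$element %in% c("N", "P"), mol$charge,
                ifelse(mol$charge < 0, mol$charge, 0L))
  as.integer(pmax(0L, h + ifelse(is.na(mol$hcount), adj, 0L)))
}

heavy_degree <- function(mol) {
  n <- n_atoms(mol)
  deg <- integer(n)
  if (nrow(mol$bonds)) {
    tb <- table(factor(c(mol$bonds$i, mol$bonds$j), levels = seq_len(n)))
    deg <- as.integer(tb)
  }
  deg
}

adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$i[k]]] <- rbind(adj[[b$i[k]]], c(b$j[k], b$order[k]))
      adj[[b$j[k]]] <- rbind(adj[[b$j[k]]], c(b$i[k], b$order[k]))
    }
  }
  adj
}

#' Molecular formula (Hill order)
#' @param mol a `mol_graph`.
#' @return a character scalar such as `"C6H6"`.
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$element)
  nh <- sum(mol$hcount)
  syms <- names(counts)
  ord <- c("C", sort(setdiff(syms, "C")))
  parts <- character(0)
  for (s in ord[ord %in% syms]) {
    parts <- c(parts, paste0(s, if (counts[[s]] > 1) counts[[s]] else ""))
    if (s == "C" && nh > 0) parts <- c(parts, paste0("H", if (nh > 1) nh else ""))
  }
  if (!"C" %in% syms && nh > 0) parts <- c(parts, paste0("H", if (nh > 1) nh else ""))
  paste(parts, collapse = "")
}

#' Parse error condition for molecule records
#'
#' @param message error text.
#' @param record_id identifier of the offending record.
#' @keywords internal
mol_parse_error <- function(message, record_id = NA_character_) {
  structure(
    class = c("mol_parse_error", "error", "condition"),
    list(message = sprintf("%s [record: %s]", message, record_id),
         call = NULL, record_id = record_id))
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I and their
#' aromatic lowercase forms), bracket atoms with explicit H counts and formal
#' charges, single/double/triple/aromatic bonds, branches, two-digit `%nn`
#' ring closures and dot-separated fragments. Stereo markers (`/ \ @`) are
#' accepted and ignored; isotopes are ignored. Implicit hydrogens follow
#' standard default valences with aromatic atoms granted one delocalized
#' bond unit.
#'
#' @param smiles a single SMILES string.
#' @param id record identifier attached to the result and to parse errors.
#' @return a `mol_graph`.
#' @export
parse_smiles <- function(smiles, id = NA_character_) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop(mol_parse_error("empty or non-character SMILES", id))
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  nch <- length(chars)
  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hcount <- integer(0)
  bi <- integer(0); bj <- integer(0); bord <- numeric(0)
  prev <- 0L              # atom the next atom bonds to; 0 = none (fragment start)
  pend_ord <- NA_real_    # explicit bond symbol awaiting the next atom
  stack <- integer(0)     # branch return points
  rings <- list()         # ring-closure digit -> c(atom, order or NA)
  pos <- 1L

  add_atom <- function(sym, arom, chg, hc) {
    element <<- c(element, sym); aromatic <<- c(aromatic, arom)
    charge <<- c(charge, chg); hcount <<- c(hcount, hc)
    a <- length(element)
    if (prev > 0L) {
      ord <- pend_ord
      if (is.na(ord)) ord <- if (arom && aromatic[prev]) 1.5 else 1
      bi <<- c(bi, prev); bj <<- c(bj, a); bord <<- c(bord, ord)
    }
    pend_ord <<- NA_real_
    prev <<- a
  }

  while (pos <= nch) {
    ch <- chars[pos]
    nxt <- if (pos < nch) chars[pos + 1L] else ""
    if (ch == "(") {
      if (prev == 0L) stop(mol_parse_error("branch before any atom", id))
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop(mol_parse_error("unmatched ')'", id))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pend_ord <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5)
      pos <- pos + 1L
    } else if (ch %in% c("/", "\\")) {     # stereo bond -> single
      pend_ord <- 1; pos <- pos + 1L
    } else if (ch == ".") {
      prev <- 0L; pend_ord <- NA_real_; pos <- pos + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (pos + 2L > nch) stop(mol_parse_error("truncated %nn ring closure", id))
        key <- paste0(chars[pos + 1L], chars[pos + 2L]); pos <- pos + 3L
      } else {
        key <- ch; pos <- pos + 1L
      }
      if (prev == 0L) stop(mol_parse_error("ring closure before any atom", id))
      if (is.null(rings[[key]])) {
        rings[[key]] <- c(prev, pend_ord)
      } else {
        open <- rings[[key]]; rings[[key]] <- NULL
        ord <- pend_ord
        if (is.na(ord)) ord <- open[2L]
        if (is.na(ord)) ord <- if (aromatic[prev] && aromatic[open[1L]]) 1.5 else 1
        if (open[1L] == prev) stop(mol_parse_error("self ring closure", id))
        bi <- c(bi, open[1L]); bj <- c(bj, prev); bord <- c(bord, ord)
      }
      pend_ord <- NA_real_
    } else if (ch == "[") {
      close <- pos
      while (close <= nch && chars[close] != "]") close <- close + 1L
      if (close > nch) stop(mol_parse_error("unterminated bracket atom", id))
      body <- paste(chars[(pos + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2}H?[0-9]*)((?:\\+\\+?|--?|[+-][0-9]+)?)$",
        body))[[1L]]
      if (!length(m)) stop(mol_parse_error(sprintf("bad bracket atom [%s]", body), id))
      sym <- m[3L]
      arom <- sym %in% c("b", "c", "n", "o", "p", "s")
      if (arom) sym <- toupper(sym)
      if (!sym %in% .ELEMENTS$symbol || sym == "H") {
        stop(mol_parse_error(sprintf("unsupported element '%s'", sym), id))
      }
      hpart <- m[4L]
      hc <- 0L
      if (grepl("H", hpart)) {
        hn <- sub("^.*H", "", hpart)
        hc <- if (nzchar(hn)) as.integer(hn) else 1L
      }
      cpart <- m[5L]
      chg <- 0L
      if (nzchar(cpart)) {
        if (cpart %in% c("+", "-")) chg <- if (cpart == "+") 1L else -1L
        else if (cpart == "++") chg <- 2L
        else if (cpart == "--") chg <- -2L
        else chg <- as.integer(cpart)
      }
      add_atom(sym, arom, chg, hc)
      pos <- close + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      sym <- ch
      if (ch %in% c("C", "B") && nxt %in% c("l", "r")) {
        two <- paste0(ch, nxt)
        if (two %in% c("Cl", "Br")) { sym <- two; pos <- pos + 1L }
      }
      arom <- sym %in% c("b", "c", "n", "o", "p", "s")
      usym <- if (arom) toupper(sym) else sym
      if (!usym %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")) {
        stop(mol_parse_error(sprintf("unsupported atom symbol '%s'", sym), id))
      }
      add_atom(usym, arom, 0L, NA_integer_)
      pos <- pos + 1L
    } else {
      stop(mol_parse_error(sprintf("unexpected character '%s' at position %d",
                                   ch, pos), id))
    }
  }
  if (length(stack)) stop(mol_parse_error("unmatched '('", id))
  if (length(rings)) stop(mol_parse_error("unclosed ring bond", id))
  if (!length(element)) stop(mol_parse_error("no atoms parsed", id))
  mol_graph(element,
            bonds = data.frame(i = bi, j = bj, order = bord),
            aromatic = aromatic, charge = charge, hcount = hcount,
            source_id = id)
}

#' Drug-likeness descriptors
#'
#' Molecular weight (implicit hydrogens included), a coarse additive logP
#' estimate, and Lipinski hydrogen-bond donor/acceptor counts (donors = H on
#' N or O; acceptors = N + O atom count).
#'
#' The logP estimator is a deliberately simple per-atom contribution scheme
#' (aromatic C +0.30, aliphatic C +0.20, N -0.70, O -0.55, S +0.10, F +0.20,
#' Cl +0.65, Br +0.85, I +1.00, P -0.40, B -0.10, polar H -0.10 each). It is
#' not a calibrated Crippen model; it is monotone in hydrophobic content,
#' which is what the drug-likeness filter and the synthetic library need.
#'
#' @param mol a `mol_graph`.
#' @return named list with `mw`, `logp`, `hbd`, `hba`.
#' @export
mol_descriptors <- function(mol) {
  mw <- sum(.ELEMENTS[mol$element, "mass"]) + sum(mol$hcount) * 1.008
  contrib <- c(B = -0.10, C = 0.20, N = -0.70, O = -0.55, F = 0.20,
               P = -0.40, S = 0.10, Cl = 0.65, Br = 0.85, I = 1.00)
  base <- contrib[mol$element]
  base[mol$element == "C" & mol$aromatic] <- 0.30
  polar_h <- sum(mol$hcount[mol$element %in% c("N", "O")])
  logp <- sum(base) - 0.10 * polar_h
  list(mw = mw, logp = unname(logp),
       hbd = polar_h, hba = sum(mol$element %in% c("N", "O")))
}

#' Read a SMILES library (.smi)
#'
#' One record per line: whitespace-separated SMILES string and identifier.
#' Lines starting with `#` and blank lines are ignored. Records lacking an
#' identifier get `mol<line>`.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return data frame with columns `smiles`, `id`.
#' @export
read_smi <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  out <- data.frame(smiles = character(length(idx)), id = character(length(idx)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    fields <- strsplit(lines[idx[k]], "[[:space:]]+")[[1L]]
    out$smiles[k] <- fields[1L]
    out$id[k] <- if (length(fields) >= 2L) fields[2L] else sprintf("mol%d", idx[k])
  }
  out
}

#' Write a SMILES library (.smi)
#' @param records data frame with `smiles` and `id` columns.
#' @param path output file.
#' @export
write_smi <- function(records, path) {
  writeLines(paste(records$smiles, records$id, sep = "\t"), path)
}
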