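# Morgan-environment substructure identifiers and circular fingerprints.
#
# Identifiers are 31-bit polynomial hashes of ECFP-style atom invariants,
# refined iteratively over bond neighborhoods. They are deterministic and
# invariant under input atom reordering (neighbor contributions are sorted
# before hashing), which is the contract downstream embedding relies on.

.HASH_P <- 2147483647  # 2^31 - 1; products stay exact in doubles

hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% .HASH_P)) %% .HASH_P
  h
}

# Per-atom identifiers for radii 0..max_radius; returns a matrix
# n_atoms x (max_radius + 1).
morgan_identifiers <- function(mol, max_radius = 1L) {
  n <- n_atoms(mol)
  deg <- heavy_degree(mol)
  adj <- adjacency_list(mol)
  ids <- matrix(0, nrow = n, ncol = max_radius + 1L)
  for (a in seq_len(n)) {
    z <- .ELEMENTS[mol$element[a], "z"]
    ids[a, 1L] <- hash_ints(c(z, deg[a], mol$hcount[a],
                              mol$charge[a] + 16L, as.integer(mol$aromatic[a])))
  }
  if (max_radius >= 1L) {
    for (r in seq_len(max_radius)) {
      for (a in seq_len(n)) {
        nb <- adj[[a]]
        if (is.null(nb)) {
          ids[a, r + 1L] <- hash_ints(c(ids[a, r], 0))
        } else {
          code <- ifelse(nb[, 2L] == 1.5, 4, nb[, 2L])
          prev <- ids[nb[, 1L], r]
          o <- order(code, prev)
          ids[a, r + 1L] <- hash_ints(c(ids[a, r], as.vector(rbind(code[o], prev[o]))))
        }
      }
    }
  }
  ids
}

#' Morgan substructure sentence
#'
#' Encodes a molecule as an ordered sequence of substructure identifiers:
#' for each heavy atom in index order, one identifier per radius in ascending
#' radius order. Identical graphs give identical sentences; permuting input
#' atom order permutes the sentence but preserves its token multiset.
#'
#' @param mol a `mol_graph`.
#' @param radii ordered integer radii, default `c(0, 1)` (the Mol2vec
#'   convention).
#' @return object of class `substructure_sentence`: list with `tokens`
#'   (character vector) and `source_id`.
#' @export
mol_to_sentence <- function(mol, radii = c(0L, 1L)) {
  stopifnot(inherits(mol, "mol_graph"))
  if (n_atoms(mol) < 1L) stop(mol_parse_error("molecule has no heavy atoms",
                                              mol$source_id))
  radii <- sort(unique(as.integer(radii)))
  ids <- morgan_identifiers(mol, max_radius = max(radii))
  toks <- as.character(t(ids[, radii + 1L, drop = FALSE]))
  structure(list(tokens = toks, source_id = mol$source_id),
            class = "substructure_sentence")
}

#' @export
print.substructure_sentence <- function(x, ...) {
  cat(sprintf("<substructure_sentence %s: %d tokens>\n",
              if (is.na(x$source_id)) "" else x$source_id, length(x$tokens)))
  invisible(x)
}

#' Circular fingerprints for a set of SMILES records
#'
#' Folds Morgan identifiers of radii 0..`radius` into a fixed-length bit
#' set per molecule. Unparseable records are reported and excluded, not
#' fatal.
#'
#' @param records data frame with `smiles` and `id` columns (see
#'   [read_smi()]).
#' @param nbits fingerprint length in bits (default 2048).
#' @param radius maximum environment radius (default 2).
#' @return object of class `fingerprint_set`: list with `ids`, `bits` (list
#'   of sorted integer vectors of set bit positions in `[0, nbits)`),
#'   `nbits`, and `failed` (ids that did not parse).
#' @export
fingerprints <- function(records, nbits = 2048L, radius = 2L) {
  stopifnot(nbits >= 2L, radius >= 0L)
  if (anyDuplicated(records$id)) stop("compound ids must be unique")
  ids <- character(0); bits <- list(); failed <- character(0)
  for (k in seq_len(nrow(records))) {
    mol <- tryCatch(parse_smiles(records$smiles[k], records$id[k]),
                    mol_parse_error = function(e) NULL)
    if (is.null(mol)) { failed <- c(failed, records$id[k]); next }
    mid <- morgan_identifiers(mol, max_radius = radius)
    ids <- c(ids, records$id[k])
    bits[[length(bits) + 1L]] <- sort(unique(as.integer(mid %% nbits)))
  }
  structure(list(ids = ids, bits = bits, nbits = as.integer(nbits),
                 failed = failed),
            class = "fingerprint_set")
}

#' Tanimoto distance between two bit sets
#'
#' `1 - |a & b| / |a | b|`; two empty sets are at distance 0.
#'
#' @param a,b integer vectors of set bit positions.
#' @return distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

# Full pairwise Tanimoto distance matrix for a fingerprint_set.
tanimoto_matrix <- function(fps) {
  n <- length(fps$ids)
  d <- matrix(0, n, n, dimnames = list(fps$ids, fps$ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- tanimoto_distance(fps$bits[[i]], fps$bits[[j]])
      }
    }
  }
  d
}
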