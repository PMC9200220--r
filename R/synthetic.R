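# Synthetic fixtures with known ground truth for every pipeline stage:
# planted-signal binding worlds (standing in for complex-derived training
# data), toy PDB complexes with known pocket membership, and fragment-grammar
# SMILES libraries spanning drug-like and non-drug-like property ranges.

#' Generate a planted-signal binding world
#'
#' Pockets and ligands carry latent vectors of dimension `k`; a pair binds
#' iff the dot product of its latents reaches a threshold (auto-tuned to a
#' target positive prevalence unless given). Observed 300-d vectors are a
#' fixed random linear map of the latents plus Gaussian noise, emulating the
#' information content of embedding-based featurization. Deterministic per
#' seed.
#'
#' @param n_pockets,n_ligands entity counts.
#' @param k latent dimension (default 4); must not exceed `dim`.
#' @param noise_sd observation noise standard deviation (default 0.1).
#' @param threshold binding threshold on latent dot products, or `NULL` to
#'   auto-tune to `prevalence`.
#' @param prevalence target fraction of binding pairs when auto-tuning
#'   (default 0.2; must land in [0.05, 0.5]).
#' @param dim observed vector dimension (default 300).
#' @param seed integer seed.
#' @return object of class `binding_world`: latent and observed matrices,
#'   the logical `labels` matrix (pockets x ligands), `threshold`, and the
#'   generating settings.
#' @export
generate_world <- function(n_pockets = 50L, n_ligands = 200L, k = 4L,
                           noise_sd = 0.1, threshold = NULL,
                           prevalence = 0.2, dim = 300L, seed = 1L) {
  if (k > dim) stop("configuration error: latent dimension k exceeds dim")
  stopifnot(n_pockets >= 1L, n_ligands >= 1L, noise_sd >= 0)
  if (is.null(threshold)) stopifnot(prevalence >= 0.05, prevalence <= 0.5)
  .with_seed(seed, {
    P <- matrix(rnorm(n_pockets * k), n_pockets, k)
    L <- matrix(rnorm(n_ligands * k), n_ligands, k)
    map_p <- matrix(rnorm(k * dim), k, dim) / sqrt(k)
    map_l <- matrix(rnorm(k * dim), k, dim) / sqrt(k)
    compat <- P %*% t(L)
    if (is.null(threshold)) {
      threshold <- as.numeric(quantile(compat, 1 - prevalence))
    }
    labels <- compat >= threshold
    pockets <- P %*% map_p +
      matrix(rnorm(n_pockets * dim, sd = noise_sd), n_pockets, dim)
    ligands <- L %*% map_l +
      matrix(rnorm(n_ligands * dim, sd = noise_sd), n_ligands, dim)
    rownames(pockets) <- sprintf("P%04d", seq_len(n_pockets))
    rownames(ligands) <- sprintf("L%05d", seq_len(n_ligands))
    dimnames(labels) <- list(rownames(pockets), rownames(ligands))
    structure(list(pocket_latent = P, ligand_latent = L,
                   pocket_obs = pockets, ligand_obs = ligands,
                   labels = labels, compat = compat, threshold = threshold,
                   k = as.integer(k), dim = as.integer(dim),
                   noise_sd = noise_sd, seed = as.integer(seed)),
              class = "binding_world")
  })
}

#' @export
print.binding_world <- function(x, ...) {
  cat(sprintf(
    "<binding_world: %d pockets x %d ligands, k = %d, prevalence %.3f>\n",
    nrow(x$pocket_obs), nrow(x$ligand_obs), x$k, mean(x$labels)))
  invisible(x)
}

#' Build a labeled pair dataset with cross-combination negatives
#'
#' Positives are all binding (pocket, ligand) pairs. Negatives pair a pocket
#' with a ligand that binds some *other* pocket, excluding every
#' true-binding pair, sampled without replacement at `ratio` negatives per
#' positive.
#'
#' @param world a [generate_world()] result.
#' @param negative_strategy only `"cross_combination"` is implemented.
#' @param ratio negative:positive count ratio (default 1).
#' @param max_positives optional cap on the number of positive pairs;
#'   when the world holds more binding pairs than this, a seeded subsample
#'   is used (keeps large screening worlds trainable at fixed dataset size).
#' @param seed sampling seed.
#' @return pair set: list with `x` (matrix `n x 2*dim`, pocket half first),
#'   `y` (0/1), `provenance` (`"positive"`/`"cross_combination"`),
#'   `pocket_id`, `ligand_id`.
#' @export
make_pair_dataset <- function(world, negative_strategy = "cross_combination",
                              ratio = 1, max_positives = NULL, seed = 1L) {
  stopifnot(inherits(world, "binding_world"),
            identical(negative_strategy, "cross_combination"), ratio > 0)
  pos <- which(world$labels, arr.ind = TRUE)
  if (!nrow(pos)) stop("world has no binding pairs")
  if (!is.null(max_positives) && nrow(pos) > max_positives) {
    pos <- .with_seed(seed + 1L,
                      pos[sample.int(nrow(pos), max_positives), ,
                          drop = FALSE])
  }
  n_neg <- round(ratio * nrow(pos))
  # candidate negatives: (p, l) non-binding where l binds >= 1 other pocket
  lig_has_partner <- colSums(world$labels) >= 1L
  cand <- which(!world$labels & rep(lig_has_partner, each = nrow(world$labels)),
                arr.ind = TRUE)
  if (nrow(cand) < n_neg) {
    stop(sprintf(
      "insufficient non-binding cross-combination pairs: need %d, have %d",
      n_neg, nrow(cand)))
  }
  neg <- .with_seed(seed, cand[sample.int(nrow(cand), n_neg), , drop = FALSE])
  all_idx <- rbind(pos, neg)
  x <- cbind(world$pocket_obs[all_idx[, 1L], , drop = FALSE],
             world$ligand_obs[all_idx[, 2L], , drop = FALSE])
  rownames(x) <- NULL
  list(x = x,
       y = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))),
       provenance = c(rep("positive", nrow(pos)),
                      rep("cross_combination", nrow(neg))),
       pocket_id = rownames(world$pocket_obs)[all_idx[, 1L]],
       ligand_id = rownames(world$ligand_obs)[all_idx[, 2L]])
}

# Heavy-atom templates (local coordinates, A) used by the toy PDB writer.
.RES_TEMPLATES <- list(
  GLY = data.frame(name = c("N", "CA", "C", "O"),
                   element = c("N", "C", "C", "O"),
                   x = c(0, 1.46, 2.00, 3.20), y = c(0, 0, 1.40, 1.50),
                   z = c(0, 0, 0, 0), stringsAsFactors = FALSE),
  ALA = data.frame(name = c("N", "CA", "C", "O", "CB"),
                   element = c("N", "C", "C", "O", "C"),
                   x = c(0, 1.46, 2.00, 3.20, 1.90),
                   y = c(0, 0, 1.40, 1.50, -0.80),
                   z = c(0, 0, 0, 0, 1.20), stringsAsFactors = FALSE))

.LIG_TEMPLATE <- data.frame(name = c("C1", "C2", "O1"),
                            element = c("C", "C", "O"),
                            x = c(0, 1.50, 2.20), y = c(0, 0, 1.00),
                            z = c(0, 0, 0), stringsAsFactors = FALSE)

.pdb_atom_line <- function(rectype, serial, name, resname, chain, resno,
                           x, y, z, element) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial, sprintf(" %-3s", name), "", resname, chain,
          resno, "", x, y, z, 1.00, 0.00, element)
}

#' Generate a toy PDB complex with known pocket membership
#'
#' Places a 3-atom reference ligand at the origin and `n_residues`
#' glycine/alanine residues along random directions, each at a prescribed
#' minimum heavy-atom distance from the ligand: exactly `n_near` residues at
#' distances within `radius`, the rest beyond it. Per-residue achieved
#' minimum distances are returned as ground-truth metadata.
#'
#' @param n_residues total residue count.
#' @param n_near number of residues planted inside the pocket radius.
#' @param radius pocket radius in Angstrom.
#' @param seed integer seed.
#' @param distances optional numeric vector (length `n_residues`) of exact
#'   minimum distances to plant, overriding the sampled ones; must be
#'   consistent with `n_near`.
#' @return list with `pdb` (character vector of PDB lines), `ligand_id`
#'   (het key), and `metadata` (data frame resno, resname, target_dist,
#'   min_dist, near).
#' @export
generate_toy_complex <- function(n_residues = 10L, n_near = 5L, radius = 10,
                                 seed = 1L, distances = NULL) {
  stopifnot(n_near >= 0L, n_near <= n_residues, radius > 0)
  if (!is.null(distances)) {
    stopifnot(length(distances) == n_residues,
              sum(distances <= radius) == n_near)
  }
  .with_seed(seed, {
    if (is.null(distances)) {
      d_near <- runif(n_near, min = 3, max = max(3.5, radius * 0.95))
      d_far <- runif(n_residues - n_near, min = radius * 1.1 + 1,
                     max = radius * 1.1 + 20)
      distances <- c(d_near, d_far)[sample.int(n_residues)]
    }
    lig <- .LIG_TEMPLATE
    lxyz <- as.matrix(lig[, c("x", "y", "z")])
    l1 <- lxyz[1L, ]                     # anchor ligand atom (origin)
    l_rest <- sweep(lxyz[-1L, , drop = FALSE], 2L, l1)
    # orthonormalize a frame whose first axis is v1
    frame_of <- function(v1) {
      v1 <- v1 / sqrt(sum(v1^2))
      a <- if (abs(v1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v2 <- a - sum(a * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
      v3 <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
              v1[3L] * v2[1L] - v1[1L] * v2[3L],
              v1[1L] * v2[2L] - v1[2L] * v2[1L])
      rbind(v1, v2, v3)
    }
    lines <- character(0)
    serial <- 1L
    meta <- data.frame(resno = seq_len(n_residues),
                       resname = character(n_residues),
                       target_dist = distances,
                       min_dist = NA_real_,
                       near = NA, stringsAsFactors = FALSE)
    for (rsd in seq_len(n_residues)) {
      resname <- if (rsd %% 2L == 0L) "ALA" else "GLY"
      tpl <- .RES_TEMPLATES[[resname]]
      tpl_xyz <- as.matrix(tpl[, c("x", "y", "z")])
      # atom offsets relative to the residue's anchor atom (its first atom);
      # expressed in a template frame whose first axis has all offsets on
      # the non-negative side
      delta <- sweep(tpl_xyz, 2L, tpl_xyz[1L, ])
      w <- colMeans(delta[-1L, , drop = FALSE])
      Tf <- frame_of(w)
      dloc <- delta %*% t(Tf)
      stopifnot(all(dloc[, 1L] >= -1e-9))
      # outward direction: away from every non-anchor ligand atom, so the
      # anchor pair (residue anchor, ligand anchor) realizes the exact
      # minimum distance d: every other pair is provably >= d
      repeat {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        if (all(l_rest %*% u <= 0)) break
      }
      Gf <- frame_of(u)
      xyz <- sweep(dloc %*% Gf, 2L, l1 + distances[rsd] * u, "+")
      # PDB columns carry 3 decimals; metadata must describe the artifact as
      # written, so distances are measured on the rounded coordinates
      xyz <- round(xyz, 3L)
      d2 <- outer(rowSums(xyz^2), rowSums(lxyz^2), "+") - 2 * xyz %*% t(lxyz)
      m <- sqrt(max(min(d2), 0))
      meta$resname[rsd] <- resname
      meta$min_dist[rsd] <- m
      for (a in seq_len(nrow(tpl))) {
        lines <- c(lines, .pdb_atom_line(
          "ATOM", serial, tpl$name[a], resname, "A", rsd,
          xyz[a, 1L], xyz[a, 2L], xyz[a, 3L], tpl$element[a]))
        serial <- serial + 1L
      }
    }
    for (a in seq_len(nrow(lig))) {
      lines <- c(lines, .pdb_atom_line(
        "HETATM", serial, lig$name[a], "LIG", "A", 900L,
        lig$x[a], lig$y[a], lig$z[a], lig$element[a]))
      serial <- serial + 1L
    }
    lines <- c(lines, "END")
    meta$near <- meta$min_dist <= radius
    stopifnot(sum(meta$near) == n_near)
    list(pdb = lines, ligand_id = "LIG:A:900", metadata = meta)
  })
}

# Fragment grammar: each fragment appends to the previous fragment's last
# atom through a single bond; terminal fragments close a chain.
.FRAG_CHAIN <- c("C", "CC", "CCC", "CCCC", "C(C)C", "c1ccccc1", "C1CCCCC1",
                 "c1ccncc1", "C1CCNCC1", "C(=O)N", "C(=O)O", "C(=O)", "CO",
                 "CN", "C(O)C", "C(N)C", "C(O)C(O)C", "OCC", "NC(C)C",
                 "c1ccc(C)cc1", "CSC")
.FRAG_TERMINAL <- c("C", "O", "N", "Cl", "F", "Br", "C(F)(F)F", "C(=O)O",
                    "C#N")

.assemble_fragments <- function(n_frag, term_prob = 0.5) {
  body <- sample(.FRAG_CHAIN, n_frag, replace = TRUE)
  smi <- paste(body, collapse = "")
  if (runif(1) < term_prob) {
    smi <- paste0(smi, sample(.FRAG_TERMINAL, 1L))
  }
  smi
}

#' Generate a drug-like-and-beyond SMILES library
#'
#' Assembles `n` unique, parseable SMILES from a fragment grammar. The
#' fragment-count distribution is heavy-tailed so that, for `n >= 200`,
#' the library contains molecules violating each Lipinski rule (heavy
#' molecules, polyols/amines with many donors and acceptors, aromatic/alkyl
#' blocks with high estimated logP) alongside clearly drug-like members.
#' Deterministic per seed.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return data frame with `smiles`, `id` columns (ids `SYN00001`, ...).
#' @export
generate_smiles_library <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  .with_seed(seed, {
    seen <- character(0)
    out <- character(n)
    k <- 0L
    while (k < n) {
      nf <- sample(1:14, 1L, prob = c(8, 10, 10, 9, 8, 7, 6, 5, 4, 4, 3, 3, 2, 2))
      smi <- .assemble_fragments(nf)
      if (smi %in% seen) {
        smi <- paste0(smi, .assemble_fragments(sample(1:3, 1L), 0))
        if (smi %in% seen) next
      }
      ok <- tryCatch({ parse_smiles(smi); TRUE },
                     mol_parse_error = function(e) FALSE)
      if (!ok) next
      k <- k + 1L
      out[k] <- smi
      seen <- c(seen, smi)
    }
    data.frame(smiles = out, id = sprintf("SYN%05d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

# Distinct scaffolds decorated with small substituents; used to test that
# fingerprint clustering recovers planted chemotype families.
.CHEMOTYPE_SCAFFOLDS <- c("c1ccccc1c1ccccc1", "C1CCCCC1C1CCCCC1",
                          "c1ccncc1C(=O)N", "C(=O)OCC(=O)OC", "CSCCSC",
                          "C1CCNCC1C1CCNCC1", "C(F)(F)FC(F)(F)",
                          "c1ccc(O)cc1C(O)")

#' Generate a library of planted chemotype families
#'
#' Each family shares one scaffold plus 1-2 small decorations, so circular
#' fingerprints separate families cleanly; family membership is returned as
#' ground truth for clustering tests.
#'
#' @param n_families number of families (at most
#'   `length(.CHEMOTYPE_SCAFFOLDS)`).
#' @param per_family molecules per family.
#' @param seed integer seed.
#' @return data frame with `smiles`, `id`, `family`.
#' @export
generate_chemotype_library <- function(n_families = 4L, per_family = 8L,
                                       seed = 1L) {
  stopifnot(n_families >= 1L, n_families <= length(.CHEMOTYPE_SCAFFOLDS),
            per_family >= 1L)
  deco <- c("C", "CC", "O", "N", "CO", "CN", "CCC", "C(C)C")
  .with_seed(seed, {
    rows <- list()
    for (f in seq_len(n_families)) {
      scaf <- .CHEMOTYPE_SCAFFOLDS[f]
      seen <- character(0)
      for (m in seq_len(per_family)) {
        repeat {
          smi <- paste0(scaf, paste(sample(deco, sample(1:2, 1L)),
                                    collapse = ""))
          if (!smi %in% seen) break
        }
        seen <- c(seen, smi)
        rows[[length(rows) + 1L]] <- data.frame(
          smiles = smi, id = sprintf("F%02dM%03d", f, m), family = f,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a DUD.E-style labeled evaluation library from a world
#'
#' Actives are the ligands that bind the chosen pocket (high latent
#' compatibility); decoys are sampled from the remaining ligands. Compounds
#' get grammar-generated SMILES for identity/clustering purposes, while
#' their screening feature vectors are the world's observed ligand vectors
#' (returned in `vectors`), so ground-truth enrichment is known exactly.
#'
#' @param world a [generate_world()] result.
#' @param pocket pocket index or id whose binders are the actives.
#' @param n_decoys decoy count (default 50 per active, capped at
#'   availability).
#' @param seed sampling seed.
#' @return object of class `labeled_library`: `compounds` (smiles, id),
#'   `active_ids`, `decoy_ids`, `vectors` (matrix, rownames = compound id),
#'   `pocket_id`, `pocket_vec`.
#' @export
generate_labeled_library <- function(world, pocket = 1L, n_decoys = NULL,
                                     seed = 1L) {
  stopifnot(inherits(world, "binding_world"))
  if (is.character(pocket)) pocket <- match(pocket, rownames(world$pocket_obs))
  stopifnot(!is.na(pocket), pocket >= 1L, pocket <= nrow(world$pocket_obs))
  act <- which(world$labels[pocket, ])
  if (!length(act)) stop("chosen pocket has no binding ligands")
  rest <- which(!world$labels[pocket, ])
  if (is.null(n_decoys)) n_decoys <- min(50L * length(act), length(rest))
  stopifnot(n_decoys >= 1L, n_decoys <= length(rest))
  dec <- .with_seed(seed, sort(rest[sample.int(length(rest), n_decoys)]))
  sel <- c(act, dec)
  ids <- rownames(world$ligand_obs)[sel]
  smi <- generate_smiles_library(length(sel), seed = seed + 7L)
  structure(list(
    compounds = data.frame(smiles = smi$smiles, id = ids,
                           stringsAsFactors = FALSE),
    active_ids = rownames(world$ligand_obs)[act],
    decoy_ids = rownames(world$ligand_obs)[dec],
    vectors = world$ligand_obs[sel, , drop = FALSE],
    pocket_id = rownames(world$pocket_obs)[pocket],
    pocket_vec = world$pocket_obs[pocket, ]),
    class = "labeled_library")
}

#' @export
print.labeled_library <- function(x, ...) {
  cat(sprintf("<labeled_library for %s: %d actives, %d decoys>\n",
              x$pocket_id, length(x$active_ids), length(x$decoy_ids)))
  invisible(x)
}
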