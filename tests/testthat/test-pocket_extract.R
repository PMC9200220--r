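# PDB parsing, pocket definition by distance to the reference ligand, and
# pocket featurization.

pdb_line <- function(rectype, serial, name, resname, chain, resno, x, y, z,
                     element, occ = 1) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial, sprintf(" %-3s", name), "", resname, chain, resno,
          "", x, y, z, occ, 0, element)
}

test_that("ATOM records fill the protein and non-water HETATM the ligands", {
  txt <- c(pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, "N"),
           pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 1.46, 0, 0, "C"),
           pdb_line("ATOM", 3, "C", "GLY", "A", 1, 2, 1.4, 0, "C"),
           pdb_line("HETATM", 4, "C1", "LIG", "A", 90, 5, 5, 5, "C"))
  s <- parse_structure(txt)
  expect_equal(sum(!s$atoms$het), 3L)
  expect_named(s$het_groups, "LIG:A:90")

  # water-only HETATM yields no het groups
  s2 <- parse_structure(c(txt[1:3],
                          pdb_line("HETATM", 4, "O", "HOH", "A", 201,
                                   9, 9, 9, "O")))
  expect_length(s2$het_groups, 0L)

  expect_error(parse_structure("REMARK nothing"), "empty-structure")
  expect_error(parse_structure(c(txt[1], "ATOM      2  CA BAD")),
               "line 2")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  ln_a <- pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C", occ = 0.4)
  ln_b <- pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 9, 9, 9, "C", occ = 0.6)
  substr(ln_a, 17, 17) <- "A"; substr(ln_b, 17, 17) <- "B"
  s <- parse_structure(c(ln_a, ln_b))
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 9)
  # tie -> altloc letter order
  ln_b2 <- sub("0.60", "0.40", ln_b, fixed = TRUE)
  s2 <- parse_structure(c(ln_b2, ln_a))
  expect_equal(s2$atoms$altloc, "A")
})

test_that("toy complexes match their generator metadata", {
  cx <- generate_toy_complex(n_residues = 9, n_near = 4, radius = 10,
                             seed = 31)
  s <- parse_structure(cx$pdb)
  # atom counts per residue follow the GLY/ALA templates
  prot <- s$atoms[!s$atoms$het, ]
  per_res <- table(prot$resno)
  expect_equal(as.integer(per_res),
               ifelse(cx$metadata$resname == "ALA", 5L, 4L))
  # brute-force min distances from coordinates reproduce metadata
  lig <- s$atoms[s$het_groups[[cx$ligand_id]], ]
  for (r in cx$metadata$resno) {
    ra <- prot[prot$resno == r, ]
    d <- Inf
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(lig))) {
      d <- min(d, sqrt((ra$x[i] - lig$x[j])^2 + (ra$y[i] - lig$y[j])^2 +
                         (ra$z[i] - lig$z[j])^2))
    }
    expect_equal(d, cx$metadata$min_dist[r], tolerance = 1e-6)
  }
  # determinism per seed
  cx2 <- generate_toy_complex(n_residues = 9, n_near = 4, radius = 10,
                              seed = 31)
  expect_identical(cx$pdb, cx2$pdb)
  # n_near = 0 gives an empty pocket
  cx0 <- generate_toy_complex(n_residues = 3, n_near = 0, radius = 8,
                              seed = 2)
  s0 <- parse_structure(cx0$pdb)
  expect_warning(p0 <- extract_pocket(s0, cx0$ligand_id,
                                      pocket_config(radius = 8)), "empty")
  expect_equal(nrow(p0$atoms), 0L)
})

test_that("pocket membership follows the distance rule exactly", {
  cx <- generate_toy_complex(n_residues = 3, n_near = 2, radius = 10,
                             seed = 7, distances = c(5, 9.9, 10.1))
  s <- parse_structure(cx$pdb)
  p <- extract_pocket(s, cx$ligand_id, pocket_config(radius = 10))
  expect_setequal(p$residues$resno, c(1L, 2L))
  # whole residues are kept
  expect_equal(nrow(p$atoms),
               sum(ifelse(cx$metadata$resname[1:2] == "ALA", 5L, 4L)))
  # a residue at distance 0 is included for any positive radius
  cx0 <- generate_toy_complex(n_residues = 2, n_near = 1, radius = 1,
                              seed = 3, distances = c(0, 30))
  s0 <- parse_structure(cx0$pdb)
  p0 <- extract_pocket(s0, cx0$ligand_id, pocket_config(radius = 0.05))
  expect_equal(p0$residues$resno, 1L)
  expect_error(extract_pocket(s, "BAD:A:1", pocket_config()), "unknown ligand")
})

test_that("pockets grow monotonically with radius", {
  for (seed in 1:3) {
    cx <- generate_toy_complex(n_residues = 12, n_near = 6, radius = 10,
                               seed = seed)
    s <- parse_structure(cx$pdb)
    prev <- integer(0)
    for (r in c(4, 8, 12, 25)) {
      p <- suppressWarnings(extract_pocket(s, cx$ligand_id,
                                           pocket_config(radius = r)))
      expect_true(all(prev %in% p$residues$resno))
      prev <- p$residues$resno
    }
  }
})

test_that("pocket pseudo-molecules carry template bonds and components", {
  # one glycine: bonds must be exactly N-CA, CA-C, C-O (template oracle)
  txt <- c(pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, "N"),
           pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 1.46, 0, 0, "C"),
           pdb_line("ATOM", 3, "C", "GLY", "A", 1, 2.0, 1.4, 0, "C"),
           pdb_line("ATOM", 4, "O", "GLY", "A", 1, 3.2, 1.5, 0, "O"),
           pdb_line("HETATM", 5, "C1", "LIG", "A", 9, 1, 1, 1, "C"))
  s <- parse_structure(txt)
  p <- extract_pocket(s, "LIG:A:9", pocket_config(radius = 10))
  mol <- pocket_to_molecule(p)
  expect_equal(length(mol$element), 4L)
  got <- sort(paste(pmin(mol$bonds$i, mol$bonds$j),
                    pmax(mol$bonds$i, mol$bonds$j)))
  expect_equal(got, sort(c("1 2", "2 3", "3 4")))

  # two residues 50 A apart -> two connected components
  cx <- generate_toy_complex(n_residues = 2, n_near = 2, radius = 60,
                             seed = 5, distances = c(5, 55))
  sp <- parse_structure(cx$pdb)
  mol2 <- pocket_to_molecule(extract_pocket(sp, cx$ligand_id,
                                            pocket_config(radius = 60)))
  expect_equal(length(unique(mol_components(mol2))), 2L)

  # determinism downstream
  s_a <- mol_to_sentence(pocket_to_molecule(p))
  s_b <- mol_to_sentence(pocket_to_molecule(p))
  expect_identical(s_a$tokens, s_b$tokens)
})

test_that("pocket featurization composes and stays additive", {
  tb <- withr::with_seed(11, toy_table(as.character(1:20), dim = 300,
                                       values = matrix(rnorm(6000), 20, 300)))
  cx <- generate_toy_complex(n_residues = 6, n_near = 3, radius = 10,
                             seed = 13)
  s <- parse_structure(cx$pdb)
  p <- extract_pocket(s, cx$ligand_id, pocket_config(radius = 10))
  v <- featurize_pocket(p, tb)
  expect_length(as.numeric(v), 300L)
  expect_true(all(is.finite(v)))

  # union of two disjoint pockets = sum of their vectors (additivity)
  half1 <- p; half1$atoms <- p$atoms[p$atoms$resno == p$atoms$resno[1], ]
  half2 <- p; half2$atoms <- p$atoms[p$atoms$resno != p$atoms$resno[1], ]
  if (min(dist(p$atoms[, c("x", "y", "z")])) > 4) {
    v12 <- featurize_pocket(p, tb)
    expect_equal(as.numeric(v12),
                 as.numeric(featurize_pocket(half1, tb)) +
                   as.numeric(featurize_pocket(half2, tb)))
  }
})
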