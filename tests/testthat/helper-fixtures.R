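# Randomized fixture builders used across the suite.  Alphabets are kept
# small so that patterns actually match, and coordinates are generated by
# the package's own synthetic generator (decoy ligands near the chain so
# contacts arise naturally).

fixture_alphabet <- c("CYS", "HIS", "ALA", "GLY", "SER", "ARG", "ASP", "LEU")

random_fixture <- function(seed, n = NULL, n_ligands = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(12:25, 1)
  if (is.null(n_ligands)) n_ligands <- sample(0:2, 1)
  codes <- sample(fixture_alphabet, n, replace = TRUE)
  spec <- fixture_spec(n, seed = seed + 1L, codes = codes,
                       n_ligands = n_ligands,
                       ligand_codes = c("ZN", "MG"),
                       pdb_id = sprintf("F%03d", seed %% 1000))
  generate_structure(spec)$structure
}

# a random valid connected pattern: <= 5 nodes, mixed edge kinds, at most
# one wildcard amino node with unrestricted polarity (keeps the oracle's
# assignment grid small)
random_pattern <- function(seed, allow_ligand = TRUE) {
  set.seed(seed)
  n_amino <- sample(1:4, 1)
  nodes <- list()
  n_free <- 0L
  for (i in seq_len(n_amino)) {
    id <- paste0("n", i)
    u <- runif(1)
    if (u < 0.2 && n_free < 1L) {
      n_free <- n_free + 1L
      nodes[[i]] <- gsp_node(id, "any_amino", polarity = "any")
    } else if (u < 0.35) {
      nodes[[i]] <- gsp_node(id, "any_amino",
                             polarity = sample(names(polarity_classes), 1))
    } else if (u < 0.5) {
      nodes[[i]] <- gsp_node(id, "any_amino",
                             allowed = sample(fixture_alphabet, 3))
    } else {
      nodes[[i]] <- gsp_node(id, "amino", name = sample(fixture_alphabet, 1))
    }
  }
  edges <- list()
  if (n_amino > 1) {
    for (i in 2:n_amino) {
      j <- if (i == 2) 1L else sample(seq_len(i - 1), 1)
      kind <- sample(c("distance", "gap", "next"), 1,
                     prob = c(0.5, 0.35, 0.15))
      if (kind == "distance") {
        lo <- runif(1, 0.5, 6)
        edges[[length(edges) + 1]] <-
          gsp_edge("distance", paste0("n", j), paste0("n", i),
                   min = lo, max = runif(1, lo, 7))
      } else if (kind == "gap") {
        gmin <- sample(1:4, 1)
        gmax <- if (runif(1) < 0.25) Inf else gmin + sample(0:3, 1)
        edges[[length(edges) + 1]] <-
          gsp_edge("gap", paste0("n", j), paste0("n", i),
                   min = gmin, max = gmax)
      } else {
        edges[[length(edges) + 1]] <-
          gsp_edge("next", paste0("n", j), paste0("n", i))
      }
    }
  }
  if (allow_ligand && runif(1) < 0.6) {
    lid <- "lig"
    nodes[[length(nodes) + 1]] <- if (runif(1) < 0.5)
      gsp_node(lid, "ligand", code = sample(c("ZN", "MG"), 1))
    else gsp_node(lid, "any_ligand")
    targets <- sample(seq_len(n_amino), min(n_amino, sample(1:2, 1)))
    for (t in targets) {
      lo <- runif(1, 0.5, 6)
      edges[[length(edges) + 1]] <-
        gsp_edge("distance", lid, paste0("n", t),
                 min = lo, max = runif(1, lo, 7))
    }
  }
  gsp_pattern(nodes, edges)
}

# in-memory database loaded with a list of structures
fixture_db <- function(structures, cath = NULL) {
  db <- gsp_db_connect(":memory:", create = TRUE)
  for (st in structures) gsp_db_load(db, st)
  if (!is.null(cath)) gsp_db_load_cath(db, cath)
  db
}

# hand-built structure with fully controlled coordinates: residues given as
# list(code3, xyz-matrix); ligands likewise
manual_structure <- function(pdb_id, residues, ligands = list()) {
  res <- lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    xyz <- matrix(r[[2]], ncol = 3)
    gsp_residue(make_ids(pdb_id, "A", seq_index = i), i, r[[1]],
                gsp_atoms(make_ids(pdb_id, "A", seq_index = i,
                                   atom_ordinal = seq_len(nrow(xyz))),
                          element = rep("C", nrow(xyz)),
                          serial = seq_len(nrow(xyz)), xyz = xyz))
  })
  lig <- lapply(seq_along(ligands), function(k) {
    l <- ligands[[k]]
    xyz <- matrix(l[[2]], ncol = 3)
    gsp_ligand(make_ids(pdb_id, "A", ligand_ordinal = k), l[[1]],
               gsp_atoms(make_ids(pdb_id, "A", ligand_ordinal = k,
                                  atom_ordinal = seq_len(nrow(xyz))),
                         element = rep("X", nrow(xyz)),
                         serial = seq_len(nrow(xyz)), xyz = xyz))
  })
  gsp_structure(pdb_id, "A", res, lig)
}
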