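# In-memory matcher: node predicates, edge semantics, and the search as a
# whole against exhaustive enumeration.

test_that("node predicates follow code, polarity class, allowed set and water rules", {
  cys <- gsp_residue("X_A_1", 1, "CYS",
                     gsp_atoms("X_A_1_1", "S", 1, matrix(0, 1, 3)))
  lys <- gsp_residue("X_A_2", 2, "LYS",
                     gsp_atoms("X_A_2_1", "C", 1, matrix(1, 1, 3)))
  glu <- gsp_residue("X_A_3", 3, "GLU",
                     gsp_atoms("X_A_3_1", "C", 1, matrix(2, 1, 3)))
  zn <- gsp_ligand("X_A_L1", "ZN",
                   gsp_atoms("X_A_L1_1", "ZN", 1, matrix(3, 1, 3)))

  expect_true(node_matches(gsp_node("n", "amino", name = "CYS"), cys))
  expect_false(node_matches(gsp_node("n", "amino", name = "CYS"), lys))
  pos <- gsp_node("n", "any_amino", polarity = "positively charged")
  expect_true(node_matches(pos, lys))
  expect_false(node_matches(pos, glu))
  expect_true(node_matches(gsp_node("n", "any_amino"), glu))
  expect_true(node_matches(gsp_node("n", "any_amino",
                                    allowed = c("GLU", "ASP")), glu))
  expect_false(node_matches(gsp_node("n", "any_amino",
                                     allowed = c("LYS")), glu))
  expect_true(node_matches(gsp_node("n", "any_ligand"), zn))
  expect_true(node_matches(gsp_node("n", "ligand", code = "ZN"), zn))
  expect_false(node_matches(gsp_node("n", "ligand", code = "MG"), zn))
  expect_error(node_matches(gsp_node("n", "amino", name = "CYS"), zn),
               "non-residue")
})

test_that("edge semantics: gap arithmetic, adjacency, distance interval", {
  st <- manual_structure("XEDG", list(
    list("CYS", c(0, 0, 0)), list("ALA", c(3.8, 0, 0)),
    list("GLY", c(7.6, 0, 0)), list("CYS", c(11.4, 0, 0)),
    list("HIS", c(15.2, 0, 0)), list("SER", c(19.0, 0, 0)),
    list("HIS", c(22.8, 0, 0))))
  ct <- build_contacts(st)
  asg <- c(a = "XEDG_A_3", b = "XEDG_A_7")
  expect_true(edge_satisfied(gsp_edge("gap", "a", "b", min = 2, max = 4),
                             asg, st, ct))                      # g = 3
  expect_false(edge_satisfied(gsp_edge("next", "a", "b"),
                              c(a = "XEDG_A_5", b = "XEDG_A_7"), st, ct))
  expect_true(edge_satisfied(gsp_edge("next", "a", "b"),
                             c(a = "XEDG_A_5", b = "XEDG_A_6"), st, ct))
  # constructed contact at 3.8 A: inside [2, 4], outside [2, 2.5]
  asg2 <- c(a = "XEDG_A_1", b = "XEDG_A_2")
  expect_true(edge_satisfied(gsp_edge("distance", "a", "b",
                                      min = 2, max = 4), asg2, st, ct))
  expect_false(edge_satisfied(gsp_edge("distance", "a", "b",
                                       min = 2, max = 2.5), asg2, st, ct))
  # unbounded gap
  expect_true(edge_satisfied(gsp_edge("gap", "a", "b", min = 1, max = "*"),
                             asg, st, ct))
})

test_that("a symmetric two-cysteine pattern produces mirror hits", {
  # exactly residues 1 and 3 lie within range of the only zinc
  st <- manual_structure("XMIR", list(
    list("CYS", c(2, 0, 0)), list("ALA", c(5, 0, 0)),
    list("CYS", c(0, 2.5, 0)), list("CYS", c(40, 0, 0))),
    ligands = list(list("ZN", c(0, 0, 0))))
  pat <- gsp_pattern(list(
    gsp_node("c1", "amino", name = "CYS"),
    gsp_node("c2", "amino", name = "CYS"),
    gsp_node("z", "ligand", code = "ZN")),
    list(gsp_edge("distance", "z", "c1", min = 0.5, max = 3),
         gsp_edge("distance", "z", "c2", min = 0.5, max = 3)))
  res <- gsp_search(pat, st)
  expect_equal(res$n_hits, 2L)          # the two mirror assignments
  expect_equal(res$n_proteins, 1L)
  expect_setequal(res$hits$node.c1, c("XMIR_A_1", "XMIR_A_3"))
  # a residue type absent from the structure: zero hits
  pat2 <- gsp_pattern(list(gsp_node("w", "amino", name = "TRP")))
  expect_equal(gsp_search(pat2, st)$n_hits, 0L)
})

test_that("search equals exhaustive enumeration on random fixtures", {
  for (s in 1:30) {
    st <- random_fixture(s, n = 15)
    pat <- random_pattern(1000 + s)
    got <- gsp_search(pat, list(st))
    want <- oracle_search(pat, list(st))
    expect_equal(got$hits, want, tolerance = 1e-12,
                 label = sprintf("seed %d", s))
    expect_equal(got$n_hits, nrow(want))
  }
})

test_that("injectivity prevents one residue from filling two amino nodes", {
  st <- manual_structure("XINJ", list(list("CYS", c(2, 0, 0))),
                         ligands = list(list("ZN", c(0, 0, 0))))
  pat <- gsp_pattern(list(
    gsp_node("c1", "amino", name = "CYS"),
    gsp_node("c2", "amino", name = "CYS"),
    gsp_node("z", "ligand", code = "ZN")),
    list(gsp_edge("distance", "z", "c1"),
         gsp_edge("distance", "z", "c2")))
  expect_equal(gsp_search(pat, st)$n_hits, 0L)
})

test_that("widening ranges or deleting edges never loses hits; order edges never add hits", {
  widen <- function(p) {
    for (i in seq_along(p$edges)) {
      e <- p$edges[[i]]
      if (e$kind == "distance") {
        p$edges[[i]]$min <- 0.5; p$edges[[i]]$max <- 7.0
      } else if (e$kind == "gap") {
        p$edges[[i]]$min <- 1; p$edges[[i]]$max <- Inf
      }
    }
    p
  }
  for (s in c(3, 9, 17, 21)) {
    sts <- list(random_fixture(s, n = 18), random_fixture(s + 50, n = 18))
    pat <- random_pattern(2000 + s)
    base <- gsp_search(pat, sts)$n_hits
    expect_gte(gsp_search(widen(pat), sts)$n_hits, base)
    if (length(pat$edges) > 1) {
      drop1 <- gsp_pattern(pat$nodes, pat$edges[-length(pat$edges)],
                           validate = FALSE)
      if (length(gsp_validate(drop1)) == 0)
        expect_gte(gsp_search(drop1, sts)$n_hits, base)
    }
  }
  # the order-restriction direction: adding gap edges to a distance-only
  # zinc pattern cannot increase the hit count
  zn2 <- parse_prosite("C-x(2)-C", "ZN")
  free <- gsp_pattern(zn2$nodes,
                      Filter(function(e) e$kind == "distance", zn2$edges))
  fx <- generate_structure(fixture_spec(24, seed = 41, pattern = zn2,
                                        n_instances = 2))
  expect_lte(gsp_search(zn2, fx$structure)$n_hits,
             gsp_search(free, fx$structure)$n_hits)
})
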