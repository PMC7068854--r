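# Relational backend: schema, loader fidelity, compiler, and equivalence
# with the in-memory engine.

test_that("schema creation yields the ten tables and is not re-runnable", {
  db <- gsp_db_connect(":memory:", create = TRUE)
  on.exit(gsp_db_disconnect(db))
  tabs <- DBI::dbListTables(db$conn)
  expect_setequal(
    intersect(tabs, c("protein", "standard_amino", "amino", "ligand",
                      "atom_amino", "atom_ligand", "distance_amino_amino",
                      "distance_ligand_amino", "next_amino_amino",
                      "protein_cath")),
    c("protein", "standard_amino", "amino", "ligand", "atom_amino",
      "atom_ligand", "distance_amino_amino", "distance_ligand_amino",
      "next_amino_amino", "protein_cath"))
  expect_error(create_schema(db), "schema-conflict")
  # 21-name reference table, FK enforcement
  expect_equal(DBI::dbGetQuery(db$conn,
               "SELECT COUNT(*) AS n FROM standard_amino")$n, 21L)
  expect_error(DBI::dbExecute(db$conn,
    "INSERT INTO amino VALUES ('X_A_1','NOPE',1,'ALA','ALA')"),
    "FOREIGN KEY")
})

test_that("loading stores n-1 adjacency rows and distances equal to build_contacts", {
  st <- random_fixture(33, n = 10, n_ligands = 1)
  ct <- build_contacts(st)
  db <- fixture_db(list(st))
  on.exit(gsp_db_disconnect(db))
  expect_equal(DBI::dbGetQuery(db$conn,
    "SELECT COUNT(*) AS n FROM next_amino_amino")$n, 9L)
  back <- DBI::dbGetQuery(db$conn,
    "SELECT amino1_id AS a_id, amino2_id AS b_id, distance
     FROM distance_amino_amino ORDER BY a_id, b_id")
  aa <- ct[ct$kind == "amino_amino", c("a_id", "b_id", "distance")]
  aa <- aa[order(aa$a_id, aa$b_id), ]
  rownames(aa) <- NULL
  expect_equal(back, aa, tolerance = 1e-6)
  la <- DBI::dbGetQuery(db$conn,
    "SELECT COUNT(*) AS n FROM distance_ligand_amino")$n
  expect_equal(la, sum(ct$kind == "ligand_amino"))
  # second load of the same entry inserts nothing
  again <- gsp_db_load(db, st)
  expect_true(again$skipped)
  expect_equal(DBI::dbGetQuery(db$conn,
    "SELECT COUNT(*) AS n FROM protein")$n, 1L)
})

test_that("a failed bulk load leaves no partial rows", {
  st <- random_fixture(34, n = 6)
  # corrupt one residue to collide on the atom primary key mid-bulk
  st$residues[[4]]$atoms$atom_id <- st$residues[[3]]$atoms$atom_id[
    rep(1, nrow(st$residues[[4]]$atoms))]
  db <- gsp_db_connect(":memory:", create = TRUE)
  on.exit(gsp_db_disconnect(db))
  expect_error(gsp_db_load(db, st))
  for (tab in c("protein", "amino", "atom_amino"))
    expect_equal(DBI::dbGetQuery(db$conn,
      sprintf("SELECT COUNT(*) AS n FROM %s", tab))$n, 0L,
      label = tab)
})

test_that("the compiler emits the expected shapes for minimal patterns", {
  # ligand-distance-amino: one join against distance_ligand_amino
  p1 <- gsp_pattern(list(gsp_node("z", "ligand", code = "ZN"),
                         gsp_node("c", "amino", name = "CYS")),
                    list(gsp_edge("distance", "z", "c", min = 1, max = 3)))
  cq <- gsp_compile(p1)
  expect_match(cq$sql, "distance_ligand_amino")
  expect_match(cq$sql, "BETWEEN")
  expect_true(any(vapply(cq$params, identical, TRUE, "ZN")))
  expect_true(any(vapply(cq$params, identical, TRUE, "CYS")))

  # a single amino node: no joins at all
  p2 <- gsp_pattern(list(gsp_node("a", "amino", name = "HIS")))
  cq2 <- gsp_compile(p2)
  expect_false(grepl("distance_", cq2$sql))
  expect_match(cq2$sql, "FROM amino a1")

  # amino-amino distance probes both stored orientations
  p3 <- gsp_pattern(list(gsp_node("a", "amino", name = "CYS"),
                         gsp_node("b", "amino", name = "HIS")),
                    list(gsp_edge("distance", "a", "b")))
  expect_match(gsp_compile(p3)$sql, "OR \\(daa1\\.amino1_id = a2\\.id")
  # injectivity condition present
  expect_match(gsp_compile(p3)$sql, "a1.id <> a2.id", fixed = TRUE)
})

test_that("executing on an empty database returns zero hits", {
  db <- gsp_db_connect(":memory:", create = TRUE)
  on.exit(gsp_db_disconnect(db))
  res <- gsp_db_search(db, parse_prosite("C-x(2)-C", "ZN"))
  expect_equal(res$n_hits, 0L)
  expect_equal(res$n_proteins, 0L)
  expect_equal(nrow(res$hits), 0L)
})

test_that("all six zinc-finger class patterns compile and execute", {
  exprs <- c("C-x(2,4)-C-x(12)-H-x(2,6)-H",
             "C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H",
             "C-x(2,4)-C-x(35,50)-C-x(2)-H",
             "C-x(5)-C-x(n)-H-x(6)-C",
             "C-x(2)-C-x(6)-C-x(5,12)-C-x(2)-C-x(6,8)-C",
             "C-P-x(1)-P-G-C-x(1)-G-x(1)-G-H-x(7)-H-R-x(4)-C")
  sts <- lapply(1:3, function(s) random_fixture(600 + s, n = 20,
                                                n_ligands = 1))
  db <- fixture_db(sts)
  on.exit(gsp_db_disconnect(db))
  for (e in exprs) {
    pat <- parse_prosite(e, ligand_code = "ZN")
    expect_length(gsp_validate(pat), 0)
    res <- gsp_db_execute(db, gsp_compile(pat))
    expect_s3_class(res, "gsp_result")
    expect_identical(res$hits, gsp_search(pat, sts)$hits)
  }
})

test_that("sql and memory backends agree on randomized structure/pattern pairs", {
  for (s in 1:25) {
    sts <- list(random_fixture(300 + s, n = 16),
                random_fixture(400 + s, n = 16))
    db <- fixture_db(sts)
    pat <- random_pattern(500 + s)
    mem <- gsp_search(pat, sts)
    sql <- gsp_db_search(db, pat)
    gsp_db_disconnect(db)
    expect_equal(sql$hits, mem$hits, tolerance = 1e-9,
                 label = sprintf("seed %d", s))
  }
})

test_that("widening a distance range returns a superset of the hits", {
  pat <- parse_prosite("C-x(2)-C", "ZN")
  fx <- generate_structure(fixture_spec(20, seed = 77, pattern = pat,
                                        n_instances = 2, pdb_id = "W001"))
  db <- fixture_db(list(fx$structure))
  on.exit(gsp_db_disconnect(db))
  narrow <- pat
  for (i in seq_along(narrow$edges)) {
    if (narrow$edges[[i]]$kind == "distance") {
      narrow$edges[[i]]$min <- 2.0
      narrow$edges[[i]]$max <- 4.0
    }
  }
  rn <- gsp_db_search(db, narrow)
  rw <- gsp_db_search(db, pat)
  key <- function(h) do.call(paste, h[grep("^node\\.", names(h))])
  expect_true(all(key(rn$hits) %in% key(rw$hits)))
})
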