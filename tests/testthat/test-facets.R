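# Facet analytics: filtering, grouping, means, export.

facet_result <- function() {
  pat <- parse_prosite("C-x(2,4)-C", "ZN")
  sts <- lapply(1:4, function(s) {
    fx <- generate_structure(fixture_spec(20, seed = 150 + s, pattern = pat,
                                          n_instances = 1,
                                          pdb_id = sprintf("P%03d", s)))
    fx$structure
  })
  list(pattern = pat, structures = sts, result = gsp_search(pat, sts))
}

test_that("filters restrict bound gaps and distances and compose", {
  fr <- facet_result()
  res <- fr$result
  expect_gt(res$n_hits, 0)
  gcol <- grep("^gap\\.", names(res$hits), value = TRUE)[1]
  eid <- sub("^gap\\.", "", gcol)
  f2 <- filter_hits(res, list(gaps = setNames(list(c(2, 2)), eid)))
  expect_true(all(f2$hits[[gcol]] == 2))
  expect_lte(f2$n_hits, res$n_hits)

  dcol <- grep("^dist\\.", names(res$hits), value = TRUE)[1]
  did <- sub("^dist\\.", "", dcol)
  f3 <- filter_hits(res, list(distances = setNames(list(c(1.5, 3.0)), did)))
  expect_true(all(f3$hits[[dcol]] >= 1.5 & f3$hits[[dcol]] <= 3.0))
  expect_true(all(rownames(f3$hits) %in% rownames(res$hits)) ||
                f3$n_hits <= res$n_hits)

  # empty predicate is the identity; unknown edge id errors
  expect_equal(filter_hits(res, list())$hits, res$hits)
  expect_error(filter_hits(res, list(gaps = list(nosuch = c(1, 2)))),
               "missing edge")
  # pdb filter
  f4 <- filter_hits(res, list(pdb_id = "P001"))
  expect_true(all(f4$hits$pdb_id == "P001"))
})

test_that("metadata predicates match classification substrings", {
  fr <- facet_result()
  meta <- data.frame(
    pdb_id = c("P001", "P002", "P003", "P004"),
    classification = c("TRANSCRIPTION/DNA", "TRANSCRIPTION",
                       "METAL BINDING PROTEIN", ""),
    organism = c("HOMO SAPIENS", "MUS MUSCULUS", "HOMO SAPIENS", ""),
    stringsAsFactors = FALSE)
  f <- filter_hits(fr$result, list(classification = "TRANSCRIPTION"),
                   meta = meta)
  expect_setequal(unique(f$hits$pdb_id), c("P001", "P002"))
  f2 <- filter_hits(fr$result, list(organism = "HOMO"), meta = meta)
  expect_setequal(unique(f2$hits$pdb_id), c("P001", "P003"))
})

test_that("gap-size groups partition the hits and carry per-edge means", {
  pat <- parse_prosite("C-x(2,4)-C", "ZN")
  sts <- lapply(1:6, function(s) {
    generate_structure(fixture_spec(20, seed = 250 + s, pattern = pat,
                                    n_instances = 1,
                                    pdb_id = sprintf("G%03d", s)))$structure
  })
  res <- gsp_search(pat, sts)
  tab <- group_by_gap_sizes(res)
  expect_equal(sum(tab$n_hits), res$n_hits)        # partition
  gcol <- grep("^gap\\.", names(tab), value = TRUE)
  expect_true(all(tab[[gcol]] %in% 2:4))
  # means recompute from the raw hits
  mcols <- grep("^mean\\.", names(tab), value = TRUE)
  for (i in seq_len(nrow(tab))) {
    sel <- res$hits[[grep("^gap\\.", names(res$hits), value = TRUE)]] ==
      tab[[gcol]][i]
    for (mc in mcols) {
      dc <- sub("^mean", "dist", mc)
      expect_equal(tab[[mc]][i], mean(res$hits[[dc]][sel]))
    }
  }
  # single-hit group: mean equals the bound distance
  single <- tab[tab$n_hits == 1, , drop = FALSE]
  if (nrow(single)) {
    sel <- res$hits[[grep("^gap\\.", names(res$hits), value = TRUE)]] ==
      single[[gcol]][1]
    expect_equal(single[[mcols[1]]][1],
                 res$hits[[sub("^mean", "dist", mcols[1])]][sel][1])
  }
})

test_that("keyword stems group classification variants together", {
  expect_equal(keyword_stem(c("TRANSCRIPTION/DNA", "TRANSCRIPTION",
                              "TRANSCRIPTION, METAL BINDING PROTEIN")),
               rep("TRANSCRIPTION", 3))
  expect_equal(keyword_stem(c("", NA)), c("UNKNOWN", "UNKNOWN"))

  fr <- facet_result()
  meta <- data.frame(
    pdb_id = sprintf("P%03d", 1:4),
    classification = c("TRANSCRIPTION/DNA", "TRANSCRIPTION",
                       "METAL BINDING PROTEIN", ""),
    stringsAsFactors = FALSE)
  tab <- group_by_keywords(fr$result, meta)
  expect_true("TRANSCRIPTION" %in% tab$group)
  expect_true("UNKNOWN" %in% tab$group)
  tr <- tab[tab$group == "TRANSCRIPTION", ]
  expect_equal(tr$n_proteins, 2L)                  # P001 and P002 merge
  expect_equal(sum(tab$n_hits), fr$result$n_hits)  # stems partition here
})

test_that("CATH grouping counts every ancestor level plus a No value bucket", {
  fr <- facet_result()
  cath <- data.frame(pdb_id = c("P001", "P002"),
                     cath_code = c("3.30.160.60", "3.30.428.10"),
                     stringsAsFactors = FALSE)
  tab <- group_by_cath(fr$result, cath)
  for (g in c("3", "3.30", "3.30.160", "3.30.160.60"))
    expect_true(g %in% tab$group)
  h1 <- tab$n_hits[tab$group == "3"]
  h4 <- tab$n_hits[tab$group == "3.30.160.60"]
  expect_gte(h1, h4)                               # hierarchy monotonicity
  nov <- tab[tab$group == "No value", ]
  expect_equal(sort(unique(
    fr$result$hits$pdb_id[!fr$result$hits$pdb_id %in% cath$pdb_id])),
    sort(unique(fr$result$hits$pdb_id[fr$result$hits$pdb_id %in%
                                        c("P003", "P004")])))
  expect_equal(nov$n_proteins, 2L)

  # no annotations at all: everything lands in No value
  tab2 <- group_by_cath(fr$result, NULL)
  expect_equal(tab2$n_hits[tab2$group == "No value"], fr$result$n_hits)
  expect_warning(group_by_cath(fr$result,
                               data.frame(pdb_id = "P001",
                                          cath_code = "3.banana")),
                 "malformed")
})

test_that("mean distances per group equal independent recomputation", {
  fr <- facet_result()
  res <- fr$result
  groups <- ifelse(res$hits$pdb_id %in% c("P001", "P002"), "g1", "g2")
  tab <- mean_distances_by_group(res, groups)
  dcols <- grep("^dist\\.", names(res$hits), value = TRUE)
  for (g in unique(groups)) {
    for (dc in dcols) {
      expect_equal(tab[[sub("^dist", "mean", dc)]][tab$group == g],
                   mean(res$hits[[dc]][groups == g]))
    }
  }
  # two hits at 2.0 and 3.0 average to 2.5 (constructed frame)
  fake <- res
  fake$hits <- res$hits[1:2, , drop = FALSE]
  fake$hits[[dcols[1]]] <- c(2, 3)
  expect_equal(mean_distances_by_group(fake)[[sub("^dist", "mean",
                                                  dcols[1])]], 2.5)
})

test_that("exports round-trip: id list lines and full JSON identity", {
  fr <- facet_result()
  ids_path <- file.path(tempdir(), "hits.ids")
  export_hits(fr$result, ids_path, mode = "ids")
  expect_equal(readLines(ids_path), unique(fr$result$hits$pdb_id))

  json_path <- file.path(tempdir(), "hits.json")
  export_hits(fr$result, json_path, mode = "json")
  back <- import_hits(json_path)
  expect_equal(back$hits, fr$result$hits, tolerance = 1e-12)
  expect_equal(back$n_hits, fr$result$n_hits)
  # facet counts recomputable from the export alone
  expect_equal(group_by_gap_sizes(back), group_by_gap_sizes(fr$result),
               tolerance = 1e-12)

  empty <- gsp_search(gsp_pattern(list(gsp_node("w", "amino",
                                                name = "TRP"))),
                      fr$structures[[1]])
  export_hits(empty, ids_path, mode = "ids")
  expect_equal(length(readLines(ids_path)), 0L)
  export_hits(empty, json_path, mode = "json")
  expect_equal(import_hits(json_path)$n_hits, 0L)
})
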