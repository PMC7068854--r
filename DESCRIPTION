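Package: gsp4r
Title: Graph-Based Structural Pattern Search for Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Search engine for protein-ligand structural patterns. A pattern
    is a labeled property graph whose nodes are amino acids (specific or
    wildcard) and ligands, and whose edges constrain minimum atom-pair
    distances, sequence adjacency, or sequence gaps. Includes a PDB-format
    ingester that pre-computes contact tables (7.0 Angstrom cutoff, largest
    chain only), a reference in-memory matcher, an equivalent compiler from
    pattern graphs to SQL over an embedded relational database, PROSITE-style
    linear pattern import (e.g. zinc-finger motifs such as
    C-x(2,4)-C-x(12)-H-x(2,6)-H), facet analytics over search results
    (keyword, CATH level, gap sizes, mean contact distances), and a
    deterministic synthetic-structure generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'structure_model.R'
    'gsp_model.R'
    'match_engine.R'
    'pdb_ingest.R'
    'sql_backend.R'
    'facets.R'
    'synthetic_fixtures.R'
    'cli.R'
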