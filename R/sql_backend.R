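# Relational realization of the search: schema, bulk loader, pattern-graph
# -> SQL compiler, and executor over an embedded SQLite database.  The
# compiler emits one sub-expression per node-edge-node structure of the
# pattern and joins them on shared node aliases and on the protein id; the
# result set is required (and property-tested) to equal the in-memory
# matcher exactly.

#' Open (or create) a structural-pattern database
#'
#' @param path database file path, or `":memory:"` for a transient
#'   in-memory database.
#' @param create create the schema if the database is empty.
#' @return handle of class `gsp_db` wrapping a DBI connection.
#' @export
gsp_db_connect <- function(path = ":memory:", create = FALSE) {
  conn <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(conn, "PRAGMA foreign_keys = ON")
  db <- structure(list(conn = conn, path = path), class = "gsp_db")
  if (create && !"protein" %in% DBI::dbListTables(conn)) create_schema(db)
  db
}

#' @rdname gsp_db_connect
#' @param db a `gsp_db` handle.
#' @export
gsp_db_disconnect <- function(db) {
  DBI::dbDisconnect(db$conn)
  invisible(NULL)
}

#' @export
print.gsp_db <- function(x, ...) {
  n <- tryCatch(
    DBI::dbGetQuery(x$conn, "SELECT COUNT(*) AS n FROM protein")$n,
    error = function(e) NA_integer_)
  cat(sprintf("<gsp_db> %s (%s proteins)\n", x$path,
              ifelse(is.na(n), "no schema,", n)))
  invisible(x)
}

#' Create the relational schema
#'
#' Creates the ten tables (protein, standard_amino, amino, ligand,
#' atom_amino, atom_ligand, distance_amino_amino, distance_ligand_amino,
#' next_amino_amino, protein_cath), their secondary indexes, and populates
#' the 21-row standard_amino reference table.  Fails cleanly when a schema
#' is already present.
#'
#' @param db a [gsp_db_connect()] handle on an empty database.
#' @export
create_schema <- function(db) {
  existing <- DBI::dbListTables(db$conn)
  if ("protein" %in% existing)
    stop("schema-conflict: database already contains a 'protein' table")
  ddl <- readLines(system.file("sql", "schema.sql", package = "gsp4r"),
                   warn = FALSE)
  ddl <- paste(ddl[!grepl("^\\s*--", ddl)], collapse = "\n")
  for (stmt in strsplit(ddl, ";", fixed = TRUE)[[1]]) {
    if (nzchar(trimws(stmt))) DBI::dbExecute(db$conn, stmt)
  }
  std <- data.frame(
    name = c(standard_amino_names, "undefined"),
    polarity = c(rep(names(polarity_classes),
                     lengths(polarity_classes)), NA_character_),
    stringsAsFactors = FALSE)
  DBI::dbAppendTable(db$conn, "standard_amino", std)
  invisible(db)
}

#' Load one structure (and its derived relations) into the database
#'
#' Inserts protein, residue, ligand, atom, contact and adjacency rows in a
#' single transaction; either everything is loaded or nothing is.  An
#' already-loaded `pdb_id` is skipped so that re-ingestion of a directory
#' is cheap.
#'
#' @param db a [gsp_db_connect()] handle with the schema in place.
#' @param structure a [gsp_structure()].
#' @param contacts optional pre-built [build_contacts()] table.
#' @param nexts optional pre-built [next_pairs()] table.
#' @param cutoff contact cutoff in Angstroms (used when `contacts` is
#'   `NULL`).
#' @return list of per-table inserted row counts; `skipped = TRUE` when
#'   the entry was already present.
#' @export
gsp_db_load <- function(db, structure, contacts = NULL, nexts = NULL,
                        cutoff = 7.0) {
  have <- DBI::dbGetQuery(db$conn,
                          "SELECT COUNT(*) AS n FROM protein WHERE id = ?",
                          params = list(structure$pdb_id))$n
  if (have > 0L) return(list(skipped = TRUE, rows = 0L))
  if (is.null(contacts)) contacts <- build_contacts(structure, cutoff)
  if (is.null(nexts)) nexts <- next_pairs(structure)
  res <- structure$residues
  counts <- list(skipped = FALSE)
  DBI::dbWithTransaction(db$conn, {
    DBI::dbAppendTable(db$conn, "protein", data.frame(
      id = structure$pdb_id, chain = structure$chain_id,
      classification = structure$classification,
      organism = structure$organism, stringsAsFactors = FALSE))
    amino <- data.frame(
      id = vapply(res, `[[`, "", "amino_id"),
      protein_id = structure$pdb_id,
      seq_index = vapply(res, `[[`, 0L, "seq_index"),
      name3 = vapply(res, `[[`, "", "code3"),
      std_name = vapply(res, `[[`, "", "std_name"),
      stringsAsFactors = FALSE)
    DBI::dbAppendTable(db$conn, "amino", amino)
    aat <- do.call(rbind, lapply(res, function(r)
      data.frame(id = r$atoms$atom_id, amino_id = r$amino_id,
                 serial = r$atoms$serial, element = r$atoms$element,
                 x = r$atoms$x, y = r$atoms$y, z = r$atoms$z,
                 stringsAsFactors = FALSE)))
    DBI::dbAppendTable(db$conn, "atom_amino", aat)
    counts$amino <- nrow(amino); counts$atom_amino <- nrow(aat)
    if (length(structure$ligands)) {
      lig <- do.call(rbind, lapply(structure$ligands, function(l)
        data.frame(id = l$ligand_id, protein_id = structure$pdb_id,
                   code = l$code3, stringsAsFactors = FALSE)))
      DBI::dbAppendTable(db$conn, "ligand", lig)
      lat <- do.call(rbind, lapply(structure$ligands, function(l)
        data.frame(id = l$atoms$atom_id, ligand_id = l$ligand_id,
                   serial = l$atoms$serial, element = l$atoms$element,
                   x = l$atoms$x, y = l$atoms$y, z = l$atoms$z,
                   stringsAsFactors = FALSE)))
      DBI::dbAppendTable(db$conn, "atom_ligand", lat)
      counts$ligand <- nrow(lig); counts$atom_ligand <- nrow(lat)
    } else counts$ligand <- 0L
    aa <- contacts[contacts$kind == "amino_amino", , drop = FALSE]
    if (nrow(aa)) {
      name_of <- stats::setNames(amino$name3, amino$id)
      DBI::dbAppendTable(db$conn, "distance_amino_amino", data.frame(
        protein_id = structure$pdb_id,
        amino1_id = aa$a_id, amino2_id = aa$b_id,
        name1 = unname(name_of[aa$a_id]), name2 = unname(name_of[aa$b_id]),
        seq1 = aa$seq_a, seq2 = aa$seq_b, distance = aa$distance,
        stringsAsFactors = FALSE))
    }
    la <- contacts[contacts$kind == "ligand_amino", , drop = FALSE]
    if (nrow(la)) {
      code_of <- stats::setNames(
        vapply(structure$ligands, `[[`, "", "code3"),
        vapply(structure$ligands, `[[`, "", "ligand_id"))
      name_of <- stats::setNames(amino$name3, amino$id)
      DBI::dbAppendTable(db$conn, "distance_ligand_amino", data.frame(
        protein_id = structure$pdb_id,
        ligand_id = la$a_id, amino_id = la$b_id,
        ligand_code = unname(code_of[la$a_id]),
        amino_name = unname(name_of[la$b_id]),
        seq = la$seq_b, distance = la$distance,
        stringsAsFactors = FALSE))
    }
    counts$distance_amino_amino <- nrow(aa)
    counts$distance_ligand_amino <- nrow(la)
    if (nrow(nexts)) {
      DBI::dbAppendTable(db$conn, "next_amino_amino", data.frame(
        protein_id = structure$pdb_id,
        amino1_id = nexts$a_id, amino2_id = nexts$b_id,
        stringsAsFactors = FALSE))
    }
    counts$next_amino_amino <- nrow(nexts)
    if (!is.null(structure$cath_codes) && length(structure$cath_codes)) {
      DBI::dbAppendTable(db$conn, "protein_cath", data.frame(
        protein_id = structure$pdb_id, cath_code = structure$cath_codes,
        stringsAsFactors = FALSE))
    }
  })
  counts
}

#' Load protein-to-CATH annotations
#'
#' @param db database handle.
#' @param map data.frame with columns `pdb_id` and `cath_code`, or the
#'   path to a 2-column tab-separated file of the same shape.
#' @return number of rows inserted, invisibly.
#' @export
gsp_db_load_cath <- function(db, map) {
  if (is.character(map) && length(map) == 1L) {
    map <- utils::read.table(map, sep = "\t", header = FALSE,
                             col.names = c("pdb_id", "cath_code"),
                             stringsAsFactors = FALSE)
  }
  DBI::dbAppendTable(db$conn, "protein_cath", data.frame(
    protein_id = toupper(map$pdb_id), cath_code = map$cath_code,
    stringsAsFactors = FALSE))
  invisible(nrow(map))
}

# ---- pattern-graph -> SQL compiler -----------------------------------------

polarity_condition <- function(alias, polarity) {
  members <- polarity_classes[[polarity]]
  sprintf("%s.std_name IN (%s)", alias,
          paste(sprintf("'%s'", members), collapse = ", "))
}

#' Compile a pattern graph into a SQL query
#'
#' Each amino node becomes an alias over the `amino` table and the ligand
#' node (if any) an alias over `ligand`; each edge contributes one
#' sub-expression (a join against `distance_amino_amino`,
#' `distance_ligand_amino` or `next_amino_amino`, or seq-index arithmetic
#' for gap edges), and the final query is the conjunction of all
#' sub-expressions plus node predicates, same-protein conditions, and
#' pairwise inequality conditions enforcing injectivity over amino nodes.
#' Amino-amino distance edges probe both stored orientations of the
#' unordered pair.
#'
#' @param pattern a valid [gsp_pattern()].
#' @return object of class `gsp_query`: `sql` (parameterized text),
#'   `params` (positional bindings), and the node/edge column maps.
#' @export
gsp_compile <- function(pattern) {
  v <- gsp_validate(pattern)
  if (length(v)) stop("invalid pattern:\n  - ", paste(v, collapse = "\n  - "))
  nids <- node_ids(pattern)
  kinds <- vapply(pattern$nodes, `[[`, "", "kind")
  amino_idx <- which(kinds %in% c("amino", "any_amino"))
  ligand_idx <- which(kinds %in% c("ligand", "any_ligand"))
  alias <- character(length(nids))
  alias[amino_idx] <- paste0("a", seq_along(amino_idx))
  alias[ligand_idx] <- "lg"
  names(alias) <- nids

  from <- c(sprintf("amino %s", alias[amino_idx]),
            if (length(ligand_idx)) sprintf("ligand %s", alias[ligand_idx]))
  where <- character()
  params <- list()
  push <- function(cond, ...) {
    where <<- c(where, cond)
    params <<- c(params, list(...))
  }

  anchor <- alias[[1]]
  sel <- c(sprintf('%s.protein_id AS "pdb_id"', anchor))
  for (i in seq_along(nids)) {
    sel <- c(sel, sprintf('%s.id AS "node.%s"', alias[i], nids[i]))
    if (i %in% amino_idx)
      sel <- c(sel, sprintf('%s.seq_index AS "seq.%s"', alias[i], nids[i]))
  }

  # node predicates
  for (i in seq_along(pattern$nodes)) {
    n <- pattern$nodes[[i]]
    al <- alias[i]
    if (n$kind == "amino") {
      push(sprintf("%s.name3 = ?", al), n$name)
    } else if (n$kind == "any_amino") {
      if (!is.null(n$allowed)) {
        where <- c(where, sprintf(
          "%s.name3 IN (%s)", al,
          paste(rep("?", length(n$allowed)), collapse = ", ")))
        params <- c(params, as.list(n$allowed))
      } else if (!is.null(n$polarity) && n$polarity != "any") {
        where <- c(where, polarity_condition(al, n$polarity))
      }
    } else if (n$kind == "ligand") {
      push(sprintf("%s.code = ?", al), n$code)
    }
    # any_ligand: no predicate (only non-water hetero groups are stored)
  }

  # same-protein conditions
  for (al in alias[-1])
    where <- c(where, sprintf("%s.protein_id = %s.protein_id", al, anchor))

  # edges
  k_dist <- 0L; k_next <- 0L
  for (e in pattern$edges) {
    ia <- match(e$a, nids); ib <- match(e$b, nids)
    if (e$kind == "distance") {
      k_dist <- k_dist + 1L
      if (ia %in% amino_idx && ib %in% amino_idx) {
        d <- paste0("daa", k_dist)
        from <- c(from, sprintf("distance_amino_amino %s", d))
        where <- c(where, sprintf(
          "((%s.amino1_id = %s.id AND %s.amino2_id = %s.id) OR (%s.amino1_id = %s.id AND %s.amino2_id = %s.id))",
          d, alias[ia], d, alias[ib], d, alias[ib], d, alias[ia]))
        push(sprintf("%s.distance BETWEEN ? AND ?", d), e$min, e$max)
        sel <- c(sel, sprintf('%s.distance AS "dist.%s"', d, e$id))
      } else {
        d <- paste0("dla", k_dist)
        lal <- if (ia %in% ligand_idx) alias[ia] else alias[ib]
        aal <- if (ia %in% ligand_idx) alias[ib] else alias[ia]
        from <- c(from, sprintf("distance_ligand_amino %s", d))
        where <- c(where, sprintf("%s.ligand_id = %s.id", d, lal),
                   sprintf("%s.amino_id = %s.id", d, aal))
        push(sprintf("%s.distance BETWEEN ? AND ?", d), e$min, e$max)
        sel <- c(sel, sprintf('%s.distance AS "dist.%s"', d, e$id))
      }
    } else if (e$kind == "next") {
      k_next <- k_next + 1L
      nx <- paste0("nx", k_next)
      from <- c(from, sprintf("next_amino_amino %s", nx))
      where <- c(where, sprintf("%s.amino1_id = %s.id", nx, alias[ia]),
                 sprintf("%s.amino2_id = %s.id", nx, alias[ib]))
    } else {  # gap: seq-index arithmetic on the amino aliases
      push(sprintf("(%s.seq_index - %s.seq_index - 1) >= ?",
                   alias[ib], alias[ia]), e$min)
      if (is.finite(e$max))
        push(sprintf("(%s.seq_index - %s.seq_index - 1) <= ?",
                     alias[ib], alias[ia]), e$max)
    }
  }

  # injectivity over amino nodes
  if (length(amino_idx) > 1L) {
    for (i in seq_along(amino_idx)[-length(amino_idx)]) {
      for (j in (i + 1L):length(amino_idx)) {
        where <- c(where,
                   sprintf("%s.id <> %s.id",
                           alias[amino_idx[i]], alias[amino_idx[j]]))
      }
    }
  }

  sql <- paste0("SELECT ", paste(sel, collapse = ",\n       "),
                "\nFROM ", paste(from, collapse = ", "),
                if (length(where))
                  paste0("\nWHERE ", paste(where, collapse = "\n  AND ")))
  structure(list(sql = sql, params = params, pattern = pattern,
                 alias = alias),
            class = "gsp_query")
}

#' @export
print.gsp_query <- function(x, ...) {
  cat("<gsp_query>\n", x$sql, "\n", sep = "")
  if (length(x$params))
    cat("params:", paste(vapply(x$params, format, ""), collapse = ", "),
        "\n")
  invisible(x)
}

#' Execute a compiled pattern query
#'
#' @param db database handle.
#' @param cq a [gsp_compile()] result (a `gsp_pattern` is accepted and
#'   compiled on the fly).
#' @return a `gsp_result`, identical in shape and content to what
#'   [gsp_search()] returns on the same data.
#' @export
gsp_db_execute <- function(db, cq) {
  if (inherits(cq, "gsp_pattern")) cq <- gsp_compile(cq)
  df <- tryCatch(
    DBI::dbGetQuery(db$conn, cq$sql,
                    params = if (length(cq$params)) unname(cq$params)),
    error = function(e) stop("SQL execution failed: ",
                             conditionMessage(e), "\n--- compiled query ---\n",
                             cq$sql))
  pattern <- cq$pattern
  nids <- node_ids(pattern)
  # derive gap sizes from the selected seq indexes, then drop them
  for (e in pattern$edges) {
    if (e$kind == "gap") {
      df[[paste0("gap.", e$id)]] <-
        as.integer(df[[paste0("seq.", e$b)]] - df[[paste0("seq.", e$a)]] - 1L)
    }
  }
  cols <- c("pdb_id", paste0("node.", nids),
            unlist(lapply(pattern$edges, function(e) {
              if (e$kind == "distance") paste0("dist.", e$id)
              else if (e$kind == "gap") paste0("gap.", e$id)
              else character()
            })))
  df <- df[, cols, drop = FALSE]
  if (nrow(df)) df <- canonical_hit_order(df) else rownames(df) <- NULL
  new_gsp_result(pattern, df)
}

#' Search a pattern through the SQL backend
#'
#' Convenience wrapper: compile, then execute.
#'
#' @inheritParams gsp_db_execute
#' @param pattern a valid [gsp_pattern()].
#' @export
gsp_db_search <- function(db, pattern) gsp_db_execute(db, gsp_compile(pattern))
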