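# Reference in-memory semantics of pattern matching.  A hit is one
# injective assignment of pattern nodes to structure entities satisfying
# every node predicate and every edge constraint; the SQL backend must
# return exactly the same hit set.

#' Does a structure entity satisfy a pattern node?
#'
#' Specific amino nodes require an exact 3-letter code match; wildcard
#' amino nodes match through their polarity class (over the residue's
#' standard name) or, when an explicit `allowed` set is present, through
#' membership of the residue code in that set.  Specific ligand nodes
#' require a code match; wildcard ligand nodes match any non-water ligand.
#'
#' @param node a [gsp_node()].
#' @param entity a [gsp_residue()] for amino-kind nodes, a [gsp_ligand()]
#'   for ligand-kind nodes.
#' @return logical scalar.
#' @export
node_matches <- function(node, entity) {
  if (is_amino_kind(node$kind)) {
    if (!inherits(entity, "gsp_residue"))
      stop("amino-kind node matched against a non-residue entity")
    if (node$kind == "amino") return(identical(entity$code3, node$name))
    if (!is.null(node$allowed)) return(entity$code3 %in% node$allowed)
    pol <- if (is.null(node$polarity)) "any" else node$polarity
    if (identical(pol, "any")) return(TRUE)
    return(entity$std_name %in% polarity_classes[[pol]])
  }
  if (!inherits(entity, "gsp_ligand"))
    stop("ligand-kind node matched against a non-ligand entity")
  if (node$kind == "ligand") return(identical(entity$code3, node$code))
  TRUE  # any_ligand: any non-water hetero group (waters never become ligands)
}

# contact lookup environment: "a<i>:a<j>" (i < j, residue indices) and
# "l<k>:a<j>" (ligand index, residue index) -> distance
contact_index <- function(contacts) {
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(contacts)))
  if (nrow(contacts)) {
    for (r in seq_len(nrow(contacts))) {
      key <- if (contacts$kind[r] == "amino_amino")
        sprintf("a%d:a%d", contacts$seq_a[r], contacts$seq_b[r])
      else
        sprintf("%s:a%d", contacts$a_id[r], contacts$seq_b[r])
      assign(key, contacts$distance[r], envir = env)
    }
  }
  env
}

lookup_contact <- function(cidx, key) {
  if (exists(key, envir = cidx, inherits = FALSE))
    get(key, envir = cidx, inherits = FALSE) else NA_real_
}

#' Is an edge constraint satisfied by an assignment?
#'
#' Distance edges are satisfied when a stored contact exists for the pair
#' and its distance lies in `[min, max]` (the pair orientation is
#' immaterial).  Next edges require `seq_index(b) == seq_index(a) + 1`.
#' Gap edges require `g = seq_index(b) - seq_index(a) - 1` to lie in
#' `[min, max]` (`max = Inf` for unbounded).
#'
#' @param edge a [gsp_edge()].
#' @param assignment named character vector, node id -> entity id
#'   (`amino_id` or `ligand_id`); both endpoints must be assigned.
#' @param structure the [gsp_structure()] the entities belong to.
#' @param contacts contact table from [build_contacts()].
#' @return logical scalar.
#' @export
edge_satisfied <- function(edge, assignment, structure, contacts) {
  ent <- function(id) {
    i <- match(id, vapply(structure$residues, `[[`, "", "amino_id"))
    if (!is.na(i)) return(list(type = "a", seq = i, id = id))
    list(type = "l", seq = NA_integer_, id = id)
  }
  ea <- ent(assignment[[edge$a]]); eb <- ent(assignment[[edge$b]])
  if (edge$kind == "distance") {
    key <- if (ea$type == "a" && eb$type == "a") {
      sprintf("a%d:a%d", min(ea$seq, eb$seq), max(ea$seq, eb$seq))
    } else if (ea$type == "l") {
      sprintf("%s:a%d", ea$id, eb$seq)
    } else sprintf("%s:a%d", eb$id, ea$seq)
    d <- lookup_contact(contact_index(contacts), key)
    return(!is.na(d) && d >= edge$min && d <= edge$max)
  }
  if (edge$kind == "next") return(eb$seq == ea$seq + 1L)
  g <- eb$seq - ea$seq - 1L
  g >= edge$min && (is.infinite(edge$max) || g <= edge$max)
}

# match a single structure; returns list of rows (named lists)
match_one <- function(g, structure, contacts) {
  nodes <- g$nodes
  nids <- node_ids(g)
  res <- structure$residues
  ligs <- structure$ligands
  cidx <- contact_index(contacts)

  # candidate entity indices per node (residue index or ligand index)
  cand <- lapply(nodes, function(n) {
    if (is_amino_kind(n$kind)) {
      which(vapply(res, function(r) node_matches(n, r), logical(1)))
    } else {
      which(vapply(ligs, function(l) node_matches(n, l), logical(1)))
    }
  })
  if (any(vapply(cand, length, integer(1)) == 0L)) return(list())

  amino_node <- vapply(nodes, function(n) is_amino_kind(n$kind), logical(1))
  ord <- order(vapply(cand, length, integer(1)))
  # edges checkable once node ord[k] is placed: both endpoints among ord[1..k]
  placed_at <- integer(length(nodes)); placed_at[ord] <- seq_along(ord)
  edges_at <- vector("list", length(nodes))
  for (e in g$edges) {
    ia <- match(e$a, nids); ib <- match(e$b, nids)
    k <- max(placed_at[ia], placed_at[ib])
    edges_at[[k]] <- c(edges_at[[k]], list(e))
  }

  check_edge <- function(e, asg) {
    ia <- match(e$a, nids); ib <- match(e$b, nids)
    va <- asg[ia]; vb <- asg[ib]
    if (e$kind == "distance") {
      key <- if (amino_node[ia] && amino_node[ib]) {
        sprintf("a%d:a%d", min(va, vb), max(va, vb))
      } else if (!amino_node[ia]) {
        sprintf("%s:a%d", ligs[[va]]$ligand_id, vb)
      } else sprintf("%s:a%d", ligs[[vb]]$ligand_id, va)
      d <- lookup_contact(cidx, key)
      return(!is.na(d) && d >= e$min && d <= e$max)
    }
    if (e$kind == "next") return(vb == va + 1L)
    gsize <- vb - va - 1L
    gsize >= e$min && (is.infinite(e$max) || gsize <= e$max)
  }

  hits <- list()
  asg <- integer(length(nodes))
  recurse <- function(k) {
    if (k > length(ord)) {
      hits[[length(hits) + 1L]] <<- asg
      return(invisible())
    }
    ni <- ord[k]
    for (v in cand[[ni]]) {
      # injectivity over amino nodes (a single ligand node needs no check,
      # and multiple ligand copies are distinct candidates anyway)
      if (amino_node[ni]) {
        conflict <- FALSE
        for (kk in seq_len(k - 1L)) {
          pj <- ord[kk]
          if (amino_node[pj] && asg[pj] == v) { conflict <- TRUE; break }
        }
        if (conflict) next
      }
      asg[ni] <<- v
      ok <- TRUE
      for (e in edges_at[[k]]) if (!check_edge(e, asg)) { ok <- FALSE; break }
      if (ok) recurse(k + 1L)
      asg[ni] <<- 0L
    }
  }
  recurse(1L)

  lapply(hits, function(a) {
    row <- list(pdb_id = structure$pdb_id)
    for (i in seq_along(nodes)) {
      eid <- if (amino_node[i]) res[[a[i]]]$amino_id else
        ligs[[a[i]]]$ligand_id
      row[[paste0("node.", nids[i])]] <- eid
    }
    for (e in g$edges) {
      ia <- match(e$a, nids); ib <- match(e$b, nids)
      if (e$kind == "distance") {
        key <- if (amino_node[ia] && amino_node[ib]) {
          sprintf("a%d:a%d", min(a[ia], a[ib]), max(a[ia], a[ib]))
        } else if (!amino_node[ia]) {
          sprintf("%s:a%d", ligs[[a[ia]]]$ligand_id, a[ib])
        } else sprintf("%s:a%d", ligs[[a[ib]]]$ligand_id, a[ia])
        row[[paste0("dist.", e$id)]] <- lookup_contact(cidx, key)
      } else if (e$kind == "gap") {
        row[[paste0("gap.", e$id)]] <- a[ib] - a[ia] - 1L
      }
    }
    row
  })
}

# assemble rows into the canonical hits data.frame
hits_frame <- function(g, rows) {
  nids <- node_ids(g)
  cols <- c("pdb_id", paste0("node.", nids),
            unlist(lapply(g$edges, function(e) {
              if (e$kind == "distance") paste0("dist.", e$id)
              else if (e$kind == "gap") paste0("gap.", e$id)
              else character()
            })))
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(
      lapply(cols, function(cn) {
        if (startsWith(cn, "dist.")) numeric()
        else if (startsWith(cn, "gap.")) integer()
        else character()
      }), cols), stringsAsFactors = FALSE, check.names = FALSE)
    return(df)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[cols], stringsAsFactors = FALSE, check.names = FALSE)))
  names(df) <- cols
  canonical_hit_order(df)
}

# deterministic hit order: by pdb_id, then node assignment columns
canonical_hit_order <- function(df) {
  keys <- df[, c("pdb_id", grep("^node\\.", names(df), value = TRUE)),
             drop = FALSE]
  df[do.call(order, unname(as.list(keys))), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

new_gsp_result <- function(pattern, hits) {
  structure(list(pattern = pattern, hits = hits,
                 n_hits = nrow(hits),
                 n_proteins = length(unique(hits$pdb_id))),
            class = "gsp_result")
}

#' Search a pattern in a set of structures (in-memory engine)
#'
#' Enumerates every hit of the pattern in every structure: an injective
#' assignment of the pattern's amino nodes to residues (plus the ligand
#' node to a ligand copy, when present) satisfying all node predicates and
#' edge constraints.  Assignments differing only by permuting equivalent
#' nodes ("mirror" hits) are distinct hits; hit counts therefore exceed
#' protein counts for order-free patterns.
#'
#' @param pattern a valid [gsp_pattern()].
#' @param structures a [gsp_structure()] or list of them.
#' @param cutoff contact cutoff in Angstroms used when contacts are built
#'   here; must be 7.0 (the storage envelope) or larger than every distance
#'   edge max.
#' @param contacts optional list of pre-built contact tables, parallel to
#'   `structures`; built on the fly when `NULL`.
#' @return object of class `gsp_result`: `hits` (one row per hit with the
#'   assigned entity ids, bound distances in Angstroms and bound gap
#'   sizes), `n_hits`, and `n_proteins` (distinct PDB entries with at
#'   least one hit).
#' @export
gsp_search <- function(pattern, structures, cutoff = 7.0, contacts = NULL) {
  v <- gsp_validate(pattern)
  if (length(v)) stop("invalid pattern:\n  - ", paste(v, collapse = "\n  - "))
  if (inherits(structures, "gsp_structure")) structures <- list(structures)
  rows <- list()
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    ct <- if (is.null(contacts)) build_contacts(s, cutoff) else contacts[[i]]
    rows <- c(rows, match_one(pattern, s, ct))
  }
  new_gsp_result(pattern, hits_frame(pattern, rows))
}

#' @export
print.gsp_result <- function(x, ...) {
  cat(sprintf("<gsp_result> %d hits in %d proteins\n",
              x$n_hits, x$n_proteins))
  if (x$n_hits > 0) {
    utils::str(utils::head(x$hits, 5), give.attr = FALSE)
    if (x$n_hits > 5) cat("  ...\n")
  }
  invisible(x)
}
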