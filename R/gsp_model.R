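# The pattern language: a graph-based structural pattern (GSP) is a labeled
# property graph.  Nodes are amino acids (specific or wildcard) and ligands
# (specific or wildcard); edges constrain contact distances, sequence
# adjacency, or sequence gaps.

node_kinds <- c("amino", "any_amino", "ligand", "any_ligand")
edge_kinds <- c("distance", "next", "gap")
polarity_values <- c("any", names(polarity_classes))

# 1-letter -> 3-letter residue code map (PROSITE symbols)
aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Create a pattern node
#'
#' @param id short unique node identifier.
#' @param kind one of `"amino"`, `"any_amino"`, `"ligand"`, `"any_ligand"`.
#' @param name 3-letter residue name; `kind = "amino"` only.
#' @param code 3-letter ligand code; `kind = "ligand"` only.
#' @param polarity polarity class for `kind = "any_amino"`; one of `"any"`,
#'   `"non-polar"`, `"polar uncharged"`, `"positively charged"`,
#'   `"negatively charged"`.  Defaults to `"any"`.
#' @param allowed optional explicit set of allowed 3-letter residue codes
#'   for an `any_amino` node (used by bracket alternations such as
#'   `[LIVMFYWC]` in linear notation).
#' @export
gsp_node <- function(id, kind, name = NULL, code = NULL,
                     polarity = NULL, allowed = NULL) {
  n <- list(id = as.character(id), kind = kind)
  if (!is.null(name)) n$name <- toupper(name)
  if (!is.null(code)) n$code <- toupper(code)
  if (identical(kind, "any_amino"))
    n$polarity <- if (is.null(polarity)) "any" else polarity
  else if (!is.null(polarity)) n$polarity <- polarity
  if (!is.null(allowed)) n$allowed <- toupper(allowed)
  structure(n, class = "gsp_node")
}

#' Create a pattern edge
#'
#' Distance edges are undirected and carry a range in Angstroms (global
#' envelope 0.5-7.0).  Next edges are directed: `b` immediately follows `a`
#' in the chain.  Gap edges are directed: between `min` and `max` residues
#' lie strictly between `a` and `b` in sequence; `max = Inf` (written `"*"`
#' in JSON and linear notation) leaves the gap unbounded above.
#'
#' @param kind `"distance"`, `"next"` or `"gap"`.
#' @param a,b endpoint node ids (for next/gap, `a` precedes `b`).
#' @param min,max range; Angstroms for distance edges (default the full
#'   0.5-7.0 envelope), residue counts for gap edges.
#' @param id optional edge identifier; assigned as `"e<k>"` by
#'   [gsp_pattern()] when missing.
#' @export
gsp_edge <- function(kind, a, b, min = NULL, max = NULL, id = NULL) {
  e <- list(kind = kind, a = as.character(a), b = as.character(b))
  if (identical(kind, "distance")) {
    e$min <- if (is.null(min)) 0.5 else as.numeric(min)
    e$max <- if (is.null(max)) 7.0 else as.numeric(max)
  } else if (identical(kind, "gap")) {
    e$min <- as.numeric(min)
    e$max <- if (is.null(max) || identical(max, "*")) Inf else as.numeric(max)
  }
  if (!is.null(id)) e$id <- as.character(id)
  structure(e, class = "gsp_edge")
}

#' Assemble a structural pattern graph
#'
#' @param nodes list of [gsp_node()] objects.
#' @param edges list of [gsp_edge()] objects (may be empty).
#' @param validate validate the assembled graph and stop on violations.
#' @return object of class `gsp_pattern`.
#' @export
gsp_pattern <- function(nodes, edges = list(), validate = TRUE) {
  k <- 0L
  edges <- lapply(edges, function(e) {
    k <<- k + 1L
    if (is.null(e$id)) e$id <- paste0("e", k)
    e
  })
  g <- structure(list(nodes = nodes, edges = edges), class = "gsp_pattern")
  if (validate) {
    v <- gsp_validate(g)
    if (length(v)) stop("invalid pattern:\n  - ", paste(v, collapse = "\n  - "))
  }
  g
}

node_ids <- function(g) vapply(g$nodes, function(n) n$id, character(1))
node_by_id <- function(g, id) g$nodes[[match(id, node_ids(g))]]
is_amino_kind <- function(kind) kind %in% c("amino", "any_amino")
is_ligand_kind <- function(kind) kind %in% c("ligand", "any_ligand")

#' Validate a structural pattern
#'
#' Checks the pattern invariants and returns violations as data rather than
#' raising: unique node ids, closed kind vocabularies, per-kind properties,
#' at most one ligand node, edge endpoints existing and of the right kind,
#' distance ranges within the 0.5-7.0 A envelope, gap ranges with
#' `min >= 1` and `max >= min` (or unbounded), and connectivity of the
#' graph read as undirected.
#'
#' @param g object to validate (normally a [gsp_pattern()]).
#' @return character vector of violations; empty for a valid pattern.
#' @export
gsp_validate <- function(g) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))
  nodes <- g$nodes
  edges <- g$edges
  if (!is.list(nodes) || length(nodes) == 0L) {
    return("pattern must contain at least one node")
  }
  ids <- vapply(nodes, function(n)
    if (is.null(n$id)) NA_character_ else as.character(n$id), character(1))
  if (anyNA(ids)) say("every node needs an id")
  if (anyDuplicated(ids)) say("duplicate node id: %s",
                              paste(unique(ids[duplicated(ids)]),
                                    collapse = ", "))
  n_ligand <- 0L
  for (n in nodes) {
    id <- if (is.null(n$id)) "<missing>" else n$id
    kind <- if (is.null(n$kind)) "<missing>" else n$kind
    if (!kind %in% node_kinds) {
      say("node %s: unknown kind '%s'", id, kind)
      next
    }
    if (is_ligand_kind(kind)) n_ligand <- n_ligand + 1L
    if (kind == "amino" && (is.null(n$name) || !grepl("^[A-Z0-9]{1,3}$", n$name)))
      say("node %s: amino node needs a 3-letter name", id)
    if (kind == "ligand" && (is.null(n$code) || !grepl("^[A-Z0-9]{1,3}$", n$code)))
      say("node %s: ligand node needs a 3-letter code", id)
    if (kind != "amino" && !is.null(n$name))
      say("node %s: 'name' is only valid on amino nodes", id)
    if (kind != "ligand" && !is.null(n$code))
      say("node %s: 'code' is only valid on ligand nodes", id)
    if (kind == "any_amino") {
      if (!is.null(n$polarity) && !n$polarity %in% polarity_values)
        say("node %s: unknown polarity '%s'", id, n$polarity)
    } else if (!is.null(n$polarity)) {
      say("node %s: 'polarity' is only valid on any_amino nodes", id)
    }
    if (!is.null(n$allowed) && kind != "any_amino")
      say("node %s: 'allowed' is only valid on any_amino nodes", id)
  }
  if (n_ligand > 1L) say("at most one ligand-kind node is allowed")
  kind_of <- stats::setNames(
    vapply(nodes, function(n)
      if (is.null(n$kind)) "" else n$kind, character(1)), ids)
  for (e in edges) {
    eid <- if (is.null(e$id)) paste0(e$kind, ":", e$a, "-", e$b) else e$id
    if (is.null(e$kind) || !e$kind %in% edge_kinds) {
      say("edge %s: unknown kind '%s'", eid,
          if (is.null(e$kind)) "<missing>" else e$kind)
      next
    }
    if (!e$a %in% ids || !e$b %in% ids) {
      say("edge %s: endpoint not in node set", eid)
      next
    }
    if (identical(e$a, e$b)) say("edge %s: self loop", eid)
    ka <- kind_of[[e$a]]; kb <- kind_of[[e$b]]
    if (e$kind == "distance") {
      if (is_ligand_kind(ka) && is_ligand_kind(kb))
        say("edge %s: distance edge cannot join two ligand nodes", eid)
      if (!is.numeric(e$min) || !is.numeric(e$max) ||
          e$min < 0.5 || e$max > 7.0 || e$min > e$max)
        say("edge %s: distance range must satisfy 0.5 <= min <= max <= 7.0",
            eid)
    } else {
      if (!is_amino_kind(ka) || !is_amino_kind(kb))
        say("edge %s: %s edges join amino-kind nodes only", eid, e$kind)
      if (e$kind == "gap") {
        if (!is.numeric(e$min) || e$min < 1 || e$min != floor(e$min))
          say("edge %s: gap min must be a positive integer", eid)
        if (!is.numeric(e$max) || (is.finite(e$max) &&
                                   (e$max < e$min || e$max != floor(e$max))))
          say("edge %s: gap max must be >= min (or unbounded)", eid)
      }
    }
  }
  # connectivity over the undirected skeleton
  if (length(v) == 0L && length(nodes) > 1L) {
    comp <- stats::setNames(seq_along(ids), ids)
    for (e in edges) {
      ca <- comp[[e$a]]; cb <- comp[[e$b]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    if (length(unique(comp)) > 1L)
      say("pattern graph is not connected")
  }
  v
}

#' @export
print.gsp_pattern <- function(x, ...) {
  kinds <- vapply(x$nodes, function(n) n$kind, character(1))
  cat(sprintf("<gsp_pattern> %d node(s) (%s), %d edge(s)\n",
              length(x$nodes),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", "),
              length(x$edges)))
  for (e in x$edges) {
    rng <- if (e$kind == "next") "" else
      sprintf(" [%s,%s]", format(e$min),
              if (is.infinite(e$max)) "*" else format(e$max))
    cat(sprintf("  %s: %s %s-%s%s\n", e$id, e$kind, e$a, e$b, rng))
  }
  invisible(x)
}

# ---- JSON serialization -----------------------------------------------------

node_json_keys <- c("id", "kind", "name", "code", "polarity", "allowed")
edge_json_keys <- c("kind", "a", "b", "min", "max", "id")

#' Serialize a pattern to JSON
#'
#' The dialect is
#' `{"nodes":[{"id","kind","name"?,"code"?,"polarity"?,"allowed"?}],`
#' `"edges":[{"kind","a","b","min"?,"max"?}]}` with an unbounded gap `max`
#' written as the string `"*"`.  Gap and next edges list the
#' sequence-earlier node as `"a"`.
#'
#' @param g a valid [gsp_pattern()].
#' @param path optional file path; when given the JSON is written there.
#' @return JSON text, invisibly when `path` is given.
#' @export
gsp_to_json <- function(g, path = NULL) {
  nodes <- lapply(g$nodes, function(n) {
    out <- n[intersect(node_json_keys, names(n))]
    class(out) <- NULL
    if (!is.null(out$allowed)) out$allowed <- as.list(out$allowed)
    out
  })
  edges <- lapply(g$edges, function(e) {
    out <- e[intersect(c("kind", "a", "b", "min", "max"), names(e))]
    class(out) <- NULL
    if (!is.null(out$max) && is.infinite(out$max)) out$max <- "*"
    out
  })
  txt <- jsonlite::toJSON(list(nodes = nodes, edges = edges),
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Parse a pattern from JSON
#'
#' Inverse of [gsp_to_json()]; unknown keys and unknown kind values are
#' rejected with the offending path in the message.
#'
#' @param txt JSON text, or a path to a JSON file.
#' @export
gsp_from_json <- function(txt) {
  if (length(txt) == 1L && !grepl("[{[]", substr(txt, 1, 1)) &&
      file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  bad <- setdiff(names(obj), c("nodes", "edges"))
  if (length(bad)) stop("unknown top-level key: ", paste(bad, collapse = ", "))
  if (is.null(obj$nodes)) stop("missing 'nodes'")
  nodes <- lapply(seq_along(obj$nodes), function(i) {
    n <- obj$nodes[[i]]
    bad <- setdiff(names(n), node_json_keys)
    if (length(bad))
      stop(sprintf("nodes[%d]: unknown key '%s'", i, bad[1]))
    if (is.null(n$id) || is.null(n$kind))
      stop(sprintf("nodes[%d]: 'id' and 'kind' are required", i))
    if (!n$kind %in% node_kinds)
      stop(sprintf("nodes[%d]: unknown kind '%s'", i, n$kind))
    gsp_node(n$id, n$kind, name = n$name, code = n$code,
             polarity = n$polarity,
             allowed = if (!is.null(n$allowed)) unlist(n$allowed))
  })
  edges <- lapply(seq_along(obj$edges), function(i) {
    e <- obj$edges[[i]]
    bad <- setdiff(names(e), edge_json_keys)
    if (length(bad))
      stop(sprintf("edges[%d]: unknown key '%s'", i, bad[1]))
    if (is.null(e$kind) || !e$kind %in% edge_kinds)
      stop(sprintf("edges[%d]: unknown kind '%s'", i,
                   if (is.null(e$kind)) "<missing>" else e$kind))
    gsp_edge(e$kind, e$a, e$b, min = e$min, max = e$max, id = e$id)
  })
  gsp_pattern(nodes, edges)
}

# ---- PROSITE-style linear notation -----------------------------------------

#' Parse a PROSITE-style linear expression into a pattern graph
#'
#' Accepts dash-separated terms: 1-letter residue codes (`C`, `H`, ...),
#' bracket alternations (`[LIVMFYWC]`, imported as a wildcard amino node
#' restricted to that set), and gap terms `x`, `x(n)`, `x(n,m)`, with
#' `x(n)` where n is literally `n` or `*` meaning an unbounded gap of at
#' least one residue.  Adjacent residue terms (no gap between them) become
#' next-edges; accumulated gap terms become one gap-edge.  Leading and
#' trailing gap terms constrain nothing and are dropped with a warning.
#'
#' When `ligand_code` is supplied a ligand node is added with a
#' default-range (0.5-7.0 A) distance edge to every amino node, turning the
#' sequence motif into a binding-site pattern (e.g.
#' `parse_prosite("C-x(2,4)-C-x(12)-H-x(2,6)-H", "ZN")` for the classical
#' Cys2His2 zinc finger).
#'
#' @param expr linear pattern expression.
#' @param ligand_code optional 3-letter ligand code.
#' @return a [gsp_pattern()].
#' @export
parse_prosite <- function(expr, ligand_code = NULL) {
  toks <- strsplit(trimws(expr), "-", fixed = TRUE)[[1]]
  if (length(toks) == 0L || !nzchar(expr)) stop("empty expression")
  nodes <- list()
  edges <- list()
  pend_min <- 0; pend_max <- 0   # accumulated gap before the next residue
  n_res <- 0L
  leading_gap <- FALSE
  prev_id <- NULL
  for (i in seq_along(toks)) {
    tok <- trimws(toks[[i]])
    if (grepl("^x(\\(.*\\))?$", tok, ignore.case = TRUE)) {
      if (tok %in% c("x", "X")) {
        pend_min <- pend_min + 1; pend_max <- pend_max + 1
      } else {
        inner <- sub("^[xX]\\((.*)\\)$", "\\1", tok)
        parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
        if (length(parts) == 1L) {
          if (parts %in% c("n", "*")) {
            pend_min <- pend_min + 1; pend_max <- Inf
          } else if (grepl("^[0-9]+$", parts)) {
            k <- as.numeric(parts)
            pend_min <- pend_min + k; pend_max <- pend_max + k
          } else stop(sprintf("unparseable gap term '%s' at position %d",
                              tok, i))
        } else if (length(parts) == 2L &&
                   grepl("^[0-9]+$", parts[1]) &&
                   grepl("^([0-9]+|\\*)$", parts[2])) {
          pend_min <- pend_min + as.numeric(parts[1])
          pend_max <- pend_max +
            if (parts[2] == "*") Inf else as.numeric(parts[2])
        } else stop(sprintf("unparseable gap term '%s' at position %d",
                            tok, i))
      }
      if (n_res == 0L) leading_gap <- TRUE
      next
    }
    # residue term
    if (grepl("^\\[[A-Za-z]+\\]$", tok)) {
      n_res <- n_res + 1L
      id <- paste0("n", n_res)
      letters1 <- strsplit(toupper(gsub("[][]", "", tok)), "")[[1]]
      bad <- setdiff(letters1, names(aa1to3))
      if (length(bad))
        stop(sprintf("unknown residue letter '%s' at position %d", bad[1], i))
      nodes[[length(nodes) + 1L]] <-
        gsp_node(id, "any_amino", allowed = unname(aa1to3[letters1]))
    } else if (grepl("^[A-Za-z]$", tok)) {
      up <- toupper(tok)
      if (!up %in% names(aa1to3))
        stop(sprintf("unknown residue letter '%s' at position %d", tok, i))
      n_res <- n_res + 1L
      id <- paste0("n", n_res)
      nodes[[length(nodes) + 1L]] <- gsp_node(id, "amino", name = aa1to3[[up]])
    } else {
      stop(sprintf("unparseable token '%s' at position %d", tok, i))
    }
    if (leading_gap) {
      warning("leading gap term constrains nothing; ignored")
      leading_gap <- FALSE
      pend_min <- 0; pend_max <- 0
    }
    if (!is.null(prev_id)) {
      if (pend_min == 0 && pend_max == 0) {
        edges[[length(edges) + 1L]] <- gsp_edge("next", prev_id, id)
      } else {
        edges[[length(edges) + 1L]] <-
          gsp_edge("gap", prev_id, id, min = pend_min, max = pend_max)
      }
    }
    prev_id <- id
    pend_min <- 0; pend_max <- 0
  }
  if (n_res == 0L) stop("expression contains no residue term")
  if (pend_min > 0 || pend_max > 0)
    warning("trailing gap term constrains nothing; ignored")
  if (!is.null(ligand_code)) {
    nodes[[length(nodes) + 1L]] <- gsp_node("lig", "ligand",
                                            code = ligand_code)
    for (k in seq_len(n_res))
      edges[[length(edges) + 1L]] <- gsp_edge("distance", "lig",
                                              paste0("n", k))
  }
  gsp_pattern(nodes, edges)
}

#' Render a linear (chain-ordered) pattern back to PROSITE-style text
#'
#' Defined for patterns whose amino nodes form a single chain under the
#' gap/next edges; the ligand node and its distance edges, if present, are
#' not rendered (linear notation cannot express them).
#'
#' @param g a [gsp_pattern()] produced by [parse_prosite()] or with the
#'   same linear shape.
#' @return single character string.
#' @export
format_prosite <- function(g) {
  aminos <- Filter(function(n) is_amino_kind(n$kind), g$nodes)
  if (length(aminos) == 0L) stop("pattern has no amino nodes")
  seq_edges <- Filter(function(e) e$kind %in% c("next", "gap"), g$edges)
  succ <- stats::setNames(
    vapply(seq_edges, function(e) e$b, character(1)),
    vapply(seq_edges, function(e) e$a, character(1)))
  aid <- vapply(aminos, function(n) n$id, character(1))
  start <- setdiff(aid, unname(succ))
  if (length(start) != 1L && length(aminos) > 1L)
    stop("pattern is not a single chain; cannot render linearly")
  sym <- function(n) {
    if (n$kind == "amino") {
      m <- names(aa1to3)[match(n$name, aa1to3)]
      if (is.na(m)) stop("no 1-letter code for ", n$name)
      m
    } else if (!is.null(n$allowed)) {
      paste0("[", paste(names(aa1to3)[match(n$allowed, aa1to3)],
                        collapse = ""), "]")
    } else "x"
  }
  cur <- if (length(aminos) == 1L) aid else start
  out <- sym(node_by_id(g, cur))
  while (cur %in% names(succ)) {
    nxt <- succ[[cur]]
    e <- Filter(function(e) identical(e$a, cur) && identical(e$b, nxt),
                seq_edges)[[1]]
    if (e$kind == "gap") {
      gaptxt <- if (is.infinite(e$max)) {
        if (e$min == 1) "x(n)" else sprintf("x(%d,*)", as.integer(e$min))
      } else if (e$min == e$max) {
        sprintf("x(%d)", as.integer(e$min))
      } else sprintf("x(%d,%d)", as.integer(e$min), as.integer(e$max))
      out <- paste0(out, "-", gaptxt)
    }
    out <- paste0(out, "-", sym(node_by_id(g, nxt)))
    cur <- nxt
  }
  out
}
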