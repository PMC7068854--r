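# Post-search analytics: filtering hits by bound values and metadata,
# grouping by gap-size tuples / classification keywords / CATH levels, and
# mean contact distances per group.  All summaries are recomputable from
# the exported JSON alone.

edge_cols <- function(result, prefix) {
  grep(paste0("^", prefix, "\\."), names(result$hits), value = TRUE)
}

#' Filter search hits by bound values and metadata
#'
#' Every element of `spec` is a conjunction term; hits satisfying all of
#' them are kept and the counts recomputed.  Supported terms:
#' \describe{
#'   \item{gaps}{named list, edge id -> `c(min, max)` on the bound gap size.}
#'   \item{distances}{named list, edge id -> `c(min, max)` Angstroms on the
#'     bound distance.}
#'   \item{pdb_id}{character vector of PDB ids to keep.}
#'   \item{classification, organism}{substring (fixed, case-insensitive)
#'     matched against the per-protein metadata in `meta`.}
#'   \item{nodes}{named list, node id -> allowed entity ids (resolved
#'     identity of a wildcard node).}
#' }
#'
#' @param result a `gsp_result`.
#' @param spec list of predicate terms (empty list = identity).
#' @param meta optional data.frame (`pdb_id`, `classification`,
#'   `organism`) needed by the metadata terms.
#' @return a filtered `gsp_result`.
#' @export
filter_hits <- function(result, spec = list(), meta = NULL) {
  hits <- result$hits
  keep <- rep(TRUE, nrow(hits))
  for (kind in c("gaps", "distances")) {
    prefix <- if (kind == "gaps") "gap." else "dist."
    for (eid in names(spec[[kind]])) {
      col <- paste0(prefix, eid)
      if (!col %in% names(hits))
        stop("predicate names a missing edge: ", eid)
      rng <- spec[[kind]][[eid]]
      keep <- keep & hits[[col]] >= rng[1] & hits[[col]] <= rng[2]
    }
  }
  if (!is.null(spec$pdb_id)) keep <- keep & hits$pdb_id %in% spec$pdb_id
  for (field in c("classification", "organism")) {
    if (!is.null(spec[[field]])) {
      if (is.null(meta)) stop("'", field, "' predicate needs meta")
      m <- meta[[field]][match(hits$pdb_id, meta$pdb_id)]
      m[is.na(m)] <- ""
      keep <- keep & grepl(spec[[field]], m, fixed = TRUE,
                           ignore.case = FALSE)
    }
  }
  for (nid in names(spec$nodes)) {
    col <- paste0("node.", nid)
    if (!col %in% names(hits)) stop("predicate names a missing node: ", nid)
    keep <- keep & hits[[col]] %in% spec$nodes[[nid]]
  }
  new_gsp_result(result$pattern, hits[keep, , drop = FALSE] |>
                   (\(d) { rownames(d) <- NULL; d })())
}

facet_frame <- function(group, hits_by_group) {
  do.call(rbind, lapply(seq_along(group), function(i) {
    h <- hits_by_group[[i]]
    data.frame(group = group[i], n_hits = nrow(h),
               n_proteins = length(unique(h$pdb_id)),
               stringsAsFactors = FALSE)
  }))
}

#' Group hits by their realized gap-size tuple
#'
#' One group per distinct combination of bound gap sizes (the sub-pattern
#' a hit realizes), with hit/protein counts and, when the pattern has
#' ligand-amino distance edges, the per-edge mean distance.
#'
#' @param result a `gsp_result` whose pattern has at least one gap edge.
#' @return data.frame with one row per gap-size tuple: the gap columns,
#'   `n_hits`, `n_proteins`, and `mean.<edge>` columns.
#' @export
group_by_gap_sizes <- function(result) {
  gcols <- edge_cols(result, "gap")
  if (length(gcols) == 0L) stop("pattern has no gap edges")
  hits <- result$hits
  dcols <- edge_cols(result, "dist")
  key <- do.call(paste, c(hits[gcols], sep = "|"))
  out <- lapply(unique(key), function(k) {
    h <- hits[key == k, , drop = FALSE]
    row <- h[1, gcols, drop = FALSE]
    row$n_hits <- nrow(h)
    row$n_proteins <- length(unique(h$pdb_id))
    for (dc in dcols) row[[sub("^dist", "mean", dc)]] <- mean(h[[dc]])
    row
  })
  out <- do.call(rbind, out)
  out <- out[do.call(order, unname(as.list(out[gcols]))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a classification string to its keyword stem
#'
#' The stem is the uppercased leading token sequence before any `/` or
#' `,`; an empty classification stems to `"UNKNOWN"`.  This reproduces the
#' visible grouping of classification keywords (e.g. `"TRANSCRIPTION"`,
#' `"TRANSCRIPTION/DNA"` and `"TRANSCRIPTION, METAL BINDING PROTEIN"` all
#' stem to `"TRANSCRIPTION"`) without any text mining.
#'
#' @param x character vector of classification strings.
#' @return character vector of stems.
#' @export
keyword_stem <- function(x) {
  x[is.na(x)] <- ""
  stem <- toupper(trimws(sub("[/,].*$", "", x)))
  stem[!nzchar(stem)] <- "UNKNOWN"
  stem
}

#' Group hits by classification keyword stem
#'
#' @param result a `gsp_result`.
#' @param meta data.frame with columns `pdb_id` and `classification`.
#' @return data.frame `group`, `n_hits`, `n_proteins`, ordered by
#'   decreasing hit count.
#' @export
group_by_keywords <- function(result, meta) {
  hits <- result$hits
  cls <- meta$classification[match(hits$pdb_id, meta$pdb_id)]
  stem <- keyword_stem(cls)
  out <- facet_frame(unique(stem),
                     lapply(unique(stem), function(s)
                       hits[stem == s, , drop = FALSE]))
  out <- out[order(-out$n_hits, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group hits by CATH hierarchy level
#'
#' Counts hits at each of the four CATH levels (Class, Architecture,
#' Topology/fold, Homologous superfamily): a protein annotated
#' `3.30.160.60` is counted under `3`, `3.30`, `3.30.160` and
#' `3.30.160.60`.  Hits on proteins with no (or malformed) annotation fall
#' into a `"No value"` bucket at every level; a malformed code raises a
#' warning.  A protein with several annotations contributes its hits to
#' each of them.
#'
#' @param result a `gsp_result`.
#' @param cath optional data.frame with columns `pdb_id` and `cath_code`
#'   (dotted codes, 1-4 integer components).
#' @return data.frame `level` (1-4), `group` (code prefix or
#'   `"No value"`), `n_hits`, `n_proteins`.
#' @export
group_by_cath <- function(result, cath = NULL) {
  hits <- result$hits
  if (!is.null(cath) && nrow(cath)) {
    ok <- grepl("^[0-9]+(\\.[0-9]+){0,3}$", cath$cath_code)
    if (any(!ok)) {
      warning("malformed CATH code(s) treated as 'No value': ",
              paste(utils::head(cath$cath_code[!ok], 3), collapse = ", "))
      cath <- cath[ok, , drop = FALSE]
    }
  }
  rows <- list()
  annotated <- character()
  if (!is.null(cath) && nrow(cath)) {
    cath$pdb_id <- toupper(cath$pdb_id)
    annotated <- unique(cath$pdb_id)
    for (lvl in 1:4) {
      pref <- vapply(strsplit(cath$cath_code, ".", fixed = TRUE),
                     function(p) paste(p[seq_len(min(lvl, length(p)))],
                                       collapse = "."), "")
      full <- lengths(strsplit(cath$cath_code, ".", fixed = TRUE)) >= lvl
      sub <- data.frame(pdb_id = cath$pdb_id[full], group = pref[full],
                        stringsAsFactors = FALSE)
      sub <- unique(sub)
      for (g in unique(sub$group)) {
        pids <- sub$pdb_id[sub$group == g]
        h <- hits[hits$pdb_id %in% pids, , drop = FALSE]
        if (nrow(h) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          level = lvl, group = g, n_hits = nrow(h),
          n_proteins = length(unique(h$pdb_id)), stringsAsFactors = FALSE)
      }
    }
  }
  nov <- hits[!hits$pdb_id %in% annotated, , drop = FALSE]
  rows[[length(rows) + 1L]] <- data.frame(
    level = NA_integer_, group = "No value", n_hits = nrow(nov),
    n_proteins = length(unique(nov$pdb_id)), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$level, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean bound distances per group of hits
#'
#' For each group the arithmetic, unweighted mean over hits of every bound
#' distance edge (e.g. the four ligand-residue coordination distances of a
#' zinc-finger pattern, grouped by CATH code).
#'
#' @param result a `gsp_result` with at least one distance edge.
#' @param groups either a vector of group labels, one per hit, or `NULL`
#'   for a single overall group.
#' @return data.frame `group`, `n_hits`, one `mean.<edge>` column per
#'   distance edge.
#' @export
mean_distances_by_group <- function(result, groups = NULL) {
  dcols <- edge_cols(result, "dist")
  if (length(dcols) == 0L) stop("pattern has no distance edges")
  hits <- result$hits
  if (is.null(groups)) groups <- rep("all", nrow(hits))
  stopifnot(length(groups) == nrow(hits))
  out <- lapply(unique(groups), function(g) {
    h <- hits[groups == g, , drop = FALSE]
    row <- data.frame(group = g, n_hits = nrow(h), stringsAsFactors = FALSE)
    for (dc in dcols) row[[sub("^dist", "mean", dc)]] <- mean(h[[dc]])
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export search results
#'
#' `mode = "ids"` writes the distinct PDB ids, one per line.
#' `mode = "json"` writes the full result (pattern + hits with assignments
#' and bound values); [import_hits()] restores an identical `gsp_result`.
#'
#' @param result a `gsp_result`.
#' @param path output file path.
#' @param mode `"ids"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_hits <- function(result, path, mode = c("json", "ids")) {
  mode <- match.arg(mode)
  if (mode == "ids") {
    writeLines(unique(result$hits$pdb_id), path)
  } else {
    payload <- list(
      pattern = jsonlite::fromJSON(gsp_to_json(result$pattern),
                                   simplifyVector = FALSE),
      n_hits = result$n_hits, n_proteins = result$n_proteins,
      hits = result$hits)
    writeLines(jsonlite::toJSON(payload, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  }
  invisible(path)
}

#' @rdname export_hits
#' @export
import_hits <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"),
                            simplifyVector = TRUE, simplifyDataFrame = TRUE)
  pattern <- gsp_from_json(jsonlite::toJSON(obj$pattern, auto_unbox = TRUE))
  hits <- obj$hits
  if (is.null(hits) || length(hits) == 0L || nrow(as.data.frame(hits)) == 0L)
    return(new_gsp_result(pattern, hits_frame(pattern, list())))
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  names(hits) <- gsub("^(node|dist|gap)_", "\\1.", names(hits))
  for (cn in grep("^gap\\.", names(hits), value = TRUE))
    hits[[cn]] <- as.integer(hits[[cn]])
  new_gsp_result(pattern, canonical_hit_order(hits))
}
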