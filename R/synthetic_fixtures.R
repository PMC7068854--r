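# Deterministic generator of toy single-chain structures with known planted
# pattern instances, plus a PDB writer, so that matching, loading and
# compilation are testable without any downloads.  Geometry is synthetic:
# decoy suppression is by placement (beyond the contact cutoff), never
# probabilistic, so the returned ground truth is exact.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe a synthetic fixture
#'
#' @param n_residues chain length.
#' @param seed integer seed; fully determines the output.
#' @param codes optional explicit residue codes (length `n_residues`);
#'   drawn from the decoy alphabet when `NULL`.
#' @param n_ligands number of free-standing ligand groups to scatter near
#'   the chain (only when no pattern is planted).
#' @param ligand_codes codes for those ligands (recycled).
#' @param pattern optional [gsp_pattern()] to plant.  Supported planted
#'   patterns are binding-site motifs as produced by [parse_prosite()]
#'   with a ligand: amino nodes on a single gap/next chain, each with one
#'   distance edge to the single ligand node, and no wildcard node with
#'   polarity `"any"` (decoys could not be excluded by identity).
#' @param n_instances number of non-overlapping instances to plant.
#' @param noise positional jitter of the residue walk, Angstroms.
#' @param pdb_id 4-character id for the generated entry; derived from the
#'   seed when `NULL`.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues, seed = 1L, codes = NULL,
                         n_ligands = 0L, ligand_codes = "ZN",
                         pattern = NULL, n_instances = 0L, noise = 0.3,
                         pdb_id = NULL) {
  structure(list(n_residues = as.integer(n_residues), seed = as.integer(seed),
                 codes = codes, n_ligands = as.integer(n_ligands),
                 ligand_codes = toupper(ligand_codes), pattern = pattern,
                 n_instances = as.integer(n_instances), noise = noise,
                 pdb_id = pdb_id),
            class = "fixture_spec")
}

# codes a planted pattern's amino nodes can match; decoys must avoid these
pattern_amino_codes <- function(pattern) {
  out <- character()
  for (n in pattern$nodes) {
    if (n$kind == "amino") out <- c(out, n$name)
    else if (n$kind == "any_amino") {
      if (!is.null(n$allowed)) out <- c(out, n$allowed)
      else {
        pol <- if (is.null(n$polarity)) "any" else n$polarity
        if (pol == "any")
          stop("unsupported planted pattern: wildcard node with polarity ",
               "'any' matches every residue, so decoys cannot be excluded")
        out <- c(out, polarity_classes[[pol]])
      }
    }
  }
  unique(out)
}

# chain order of amino nodes + per-step (gap) edges; errors unless the
# pattern is a single gap/next chain with one ligand distance edge per node
planted_layout <- function(pattern) {
  kinds <- vapply(pattern$nodes, `[[`, "", "kind")
  aminos <- node_ids(pattern)[kinds %in% c("amino", "any_amino")]
  lig <- node_ids(pattern)[kinds %in% c("ligand", "any_ligand")]
  if (length(lig) != 1L)
    stop("unsupported planted pattern: needs exactly one ligand node")
  seq_edges <- Filter(function(e) e$kind %in% c("next", "gap"), pattern$edges)
  dist_edges <- Filter(function(e) e$kind == "distance", pattern$edges)
  de_amino <- vapply(dist_edges, function(e)
    if (e$a == lig) e$b else if (e$b == lig) e$a else NA_character_, "")
  if (anyNA(de_amino) || !setequal(de_amino, aminos) ||
      anyDuplicated(de_amino))
    stop("unsupported planted pattern: every amino node needs exactly one ",
         "distance edge to the ligand node")
  succ <- stats::setNames(vapply(seq_edges, `[[`, "", "b"),
                          vapply(seq_edges, `[[`, "", "a"))
  start <- setdiff(aminos, unname(succ))
  if (length(aminos) > 1L && length(start) != 1L)
    stop("unsupported planted pattern: amino nodes must form a single chain")
  order <- if (length(aminos) == 1L) aminos else {
    cur <- start; out <- cur
    while (cur %in% names(succ)) { cur <- succ[[cur]]; out <- c(out, cur) }
    out
  }
  if (!setequal(order, aminos))
    stop("unsupported planted pattern: amino nodes must form a single chain")
  steps <- if (length(order) > 1L) {
    lapply(seq_len(length(order) - 1L), function(i)
      Filter(function(e) e$a == order[i] && e$b == order[i + 1L],
             seq_edges)[[1]])
  } else list()
  list(order = order, steps = steps, ligand = lig,
       dist_edges = stats::setNames(dist_edges, de_amino))
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# residue anchors: a jittered self-avoiding walk, ~3.8 A consecutive spacing
walk_anchors <- function(n, noise) {
  anchors <- matrix(0, n, 3)
  dir <- random_unit()
  for (i in 2:max(n, 2)) {
    if (i > n) break
    for (try in 1:50) {
      cand_dir <- dir + 0.6 * random_unit()
      cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
      cand <- anchors[i - 1, ] + cand_dir * (3.8 + stats::rnorm(1, 0, noise))
      if (i == 2L ||
          min(sqrt(rowSums((anchors[seq_len(i - 2), , drop = FALSE] -
                              rep(cand, each = i - 2))^2))) > 3.0) {
        anchors[i, ] <- cand; dir <- cand_dir
        break
      }
      if (try == 50) { anchors[i, ] <- cand; dir <- cand_dir }
    }
  }
  anchors
}

residue_atoms_near <- function(anchor, n_atoms) {
  xyz <- matrix(rep(anchor, each = n_atoms), n_atoms, 3)
  if (n_atoms > 1L)
    for (j in 2:n_atoms) xyz[j, ] <- anchor + stats::runif(1, 0.5, 2) *
      random_unit()
  xyz
}

#' Generate a synthetic structure with known planted hits
#'
#' Residues sit on a jittered self-avoiding walk (about 3.8 A between
#' consecutive anchors) with 1-5 atoms each within 2 A of the anchor.
#' When a pattern is planted, each instance receives its own ligand copy
#' placed far from the chain and from other instances; the instance's
#' residues get the pattern's residue identities and one atom placed at a
#' distance drawn strictly inside each distance edge's range (at least
#' 0.1 A from either bound, so float round-trips cannot flip a hit).  All
#' other residues either lie beyond the 7.0 A cutoff from every ligand or
#' fail the node predicates, so the returned ground-truth hit set is
#' exact by construction.
#'
#' @param spec a [fixture_spec()].
#' @return list with `structure` (a [gsp_structure()]), `truth` (a
#'   ground-truth hit data.frame in [gsp_search()] layout, or `NULL` when
#'   nothing was planted) and `pattern`.
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_residues
    pat <- spec$pattern
    planted <- !is.null(pat) && spec$n_instances > 0L
    layout <- if (planted) planted_layout(pat)
    decoy_pool <- standard_amino_names
    if (planted)
      decoy_pool <- setdiff(decoy_pool, pattern_amino_codes(pat))
    if (length(decoy_pool) == 0L)
      stop("unsupported planted pattern: no decoy residue codes remain")

    codes <- if (!is.null(spec$codes)) toupper(spec$codes) else
      sample(decoy_pool, n, replace = TRUE)
    if (length(codes) != n) stop("codes must have length n_residues")

    # choose planted positions
    instances <- list()
    if (planted) {
      k <- length(layout$order)
      pos_cursor <- 1L
      for (m in seq_len(spec$n_instances)) {
        gaps <- vapply(layout$steps, function(e) {
          if (e$kind == "next") 0L else {
            hi <- if (is.infinite(e$max)) e$min + 3L else min(e$max, e$min + 3L)
            choices <- seq.int(e$min, hi)
            as.integer(choices[sample.int(length(choices), 1L)])
          }
        }, integer(1))
        span <- if (k > 1L) sum(gaps + 1L) else 0L
        start <- pos_cursor + 1L     # leave a spacer residue before
        if (start + span > n)
          stop(sprintf(
            "infeasible spec: instance %d needs positions up to %d but the chain has %d residues",
            m, start + span, n))
        pos <- start + c(0L, if (k > 1L) cumsum(gaps + 1L))
        instances[[m]] <- list(pos = pos, gaps = gaps)
        pos_cursor <- pos[k] + 1L    # spacer after
      }
    }

    anchors <- walk_anchors(n, spec$noise)
    n_atoms <- sample(1:5, n, replace = TRUE)
    xyz_list <- lapply(seq_len(n), function(i)
      residue_atoms_near(anchors[i, ], n_atoms[i]))

    ligands <- list()
    pdb_id <- if (!is.null(spec$pdb_id)) toupper(spec$pdb_id) else
      sprintf("S%03d", spec$seed %% 1000)
    chain <- "A"
    lig_positions <- list()

    if (planted) {
      lig_code <- {
        ln <- node_by_id(pat, layout$ligand)
        if (!is.null(ln$code)) ln$code else spec$ligand_codes[1]
      }
      base_x <- max(anchors[, 1]) + 60
      for (m in seq_along(instances)) {
        Lpos <- c(base_x + 120 * (m - 1), 0, 0)
        lig_positions[[m]] <- Lpos
        inst <- instances[[m]]
        dists <- numeric(length(layout$order))
        for (j in seq_along(layout$order)) {
          nid <- layout$order[j]
          node <- node_by_id(pat, nid)
          e <- layout$dist_edges[[nid]]
          d <- stats::runif(1, e$min + 0.1, e$max - 0.1)
          dists[j] <- d
          i <- inst$pos[j]
          codes[i] <- if (node$kind == "amino") node$name else {
            pool <- if (!is.null(node$allowed)) node$allowed else
              polarity_classes[[node$polarity]]
            sample(pool, 1)
          }
          u <- random_unit()
          na_i <- n_atoms[i]
          xyz <- matrix(0, na_i, 3)
          xyz[1, ] <- Lpos + u * d
          if (na_i > 1L)
            for (q in 2:na_i)
              xyz[q, ] <- Lpos + u * (d + 0.6 * (q - 1))
          xyz_list[[i]] <- xyz
        }
        instances[[m]]$dists <- dists
        ord <- length(ligands) + 1L
        ligands[[ord]] <- gsp_ligand(
          make_ids(pdb_id, chain, ligand_ordinal = ord), lig_code,
          gsp_atoms(make_ids(pdb_id, chain, ligand_ordinal = ord,
                             atom_ordinal = 1L),
                    element = substr(lig_code, 1, 2), serial = 1L,
                    xyz = matrix(Lpos, 1)))
      }
    } else if (spec$n_ligands > 0L) {
      lig_codes <- rep(spec$ligand_codes, length.out = spec$n_ligands)
      for (m in seq_len(spec$n_ligands)) {
        near <- anchors[sample(n, 1), ] + stats::runif(1, 1, 6) * random_unit()
        ord <- length(ligands) + 1L
        ligands[[ord]] <- gsp_ligand(
          make_ids(pdb_id, chain, ligand_ordinal = ord), lig_codes[m],
          gsp_atoms(make_ids(pdb_id, chain, ligand_ordinal = ord,
                             atom_ordinal = 1L),
                    element = substr(lig_codes[m], 1, 2), serial = 1L,
                    xyz = matrix(near, 1)))
      }
    }

    residues <- lapply(seq_len(n), function(i) {
      xyz <- xyz_list[[i]]
      gsp_residue(make_ids(pdb_id, chain, seq_index = i), i, codes[i],
                  gsp_atoms(make_ids(pdb_id, chain, seq_index = i,
                                     atom_ordinal = seq_len(nrow(xyz))),
                            element = c("C", rep("C", nrow(xyz) - 1L)),
                            serial = seq_len(nrow(xyz)), xyz = xyz))
    })
    st <- gsp_structure(pdb_id, chain, residues, ligands,
                        classification = "SYNTHETIC FIXTURE",
                        organism = "SYNTHETIC")

    truth <- NULL
    if (planted) truth <- planted_truth(pat, layout, st, instances)
    list(structure = st, truth = truth, pattern = pat)
  })
}

# ground truth by construction: within each instance enumerate every
# injective amino-node -> planted-slot map satisfying node predicates,
# the constructed gaps, and the constructed distances (mirror assignments
# of symmetric patterns are hits too).  Candidates are filtered by node
# predicate and distance range first, so identical-residue symmetry is
# explored without walking all k! permutations.
planted_truth <- function(pat, layout, st, instances) {
  k <- length(layout$order)
  rows <- list()
  for (m in seq_along(instances)) {
    inst <- instances[[m]]
    lig_id <- st$ligands[[m]]$ligand_id
    cand <- lapply(seq_len(k), function(j) {
      node <- node_by_id(pat, layout$order[j])
      e <- layout$dist_edges[[layout$order[j]]]
      Filter(function(s) {
        node_matches(node, st$residues[[inst$pos[s]]]) &&
          inst$dists[s] >= e$min && inst$dists[s] <= e$max
      }, seq_len(k))
    })
    slot <- integer(k)
    used <- logical(k)
    emit <- function() {
      row <- list(pdb_id = st$pdb_id)
      for (j in seq_len(k))
        row[[paste0("node.", layout$order[j])]] <-
          st$residues[[inst$pos[slot[j]]]]$amino_id
      row[[paste0("node.", layout$ligand)]] <- lig_id
      for (e in pat$edges) {
        if (e$kind == "distance") {
          aj <- match(if (e$a == layout$ligand) e$b else e$a, layout$order)
          row[[paste0("dist.", e$id)]] <- inst$dists[slot[aj]]
        } else if (e$kind == "gap") {
          ja <- match(e$a, layout$order); jb <- match(e$b, layout$order)
          row[[paste0("gap.", e$id)]] <-
            inst$pos[slot[jb]] - inst$pos[slot[ja]] - 1L
        }
      }
      rows[[length(rows) + 1L]] <<- row
    }
    dfs <- function(j) {
      if (j > k) { emit(); return(invisible()) }
      for (s in cand[[j]]) {
        if (used[s]) next
        if (j > 1L) {
          e <- layout$steps[[j - 1L]]
          g <- inst$pos[s] - inst$pos[slot[j - 1L]] - 1L
          ok <- if (e$kind == "next") g == 0L else
            g >= e$min && (is.infinite(e$max) || g <= e$max)
          if (!ok) next
        }
        slot[j] <<- s; used[s] <<- TRUE
        dfs(j + 1L)
        used[s] <<- FALSE
      }
    }
    dfs(1L)
  }
  hits_frame(pat, rows)
}

#' Replace planted residue identities with decoys (negative control)
#'
#' Breaks the node predicates of every planted instance while leaving the
#' geometry untouched; searching the planted pattern afterwards must
#' return zero hits.
#'
#' @param fx a [generate_structure()] result with planted instances.
#' @return a modified [gsp_structure()].
#' @export
negative_control <- function(fx) {
  if (is.null(fx$truth) || nrow(fx$truth) == 0L)
    stop("fixture has no planted instances")
  st <- fx$structure
  bad <- setdiff(standard_amino_names, pattern_amino_codes(fx$pattern))
  planted_ids <- unique(unlist(
    fx$truth[, grep("^node\\.", names(fx$truth)), drop = FALSE]))
  for (i in seq_along(st$residues)) {
    if (st$residues[[i]]$amino_id %in% planted_ids) {
      st$residues[[i]]$code3 <- bad[1L + (i %% length(bad))]
      st$residues[[i]]$std_name <- std_name_for(st$residues[[i]]$code3)
    }
  }
  st
}

# ---- PDB writer ------------------------------------------------------------

pdb_atom_line <- function(record, serial, name, resid, chain, resno, xyz,
                          element) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resid, chain, resno, " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

#' Write a structure as a PDB-format file
#'
#' Emits HEADER/SOURCE metadata, ATOM records for the chain, HETATM
#' records for ligand groups, TER and END.  Coordinates are written at the
#' format's 3-decimal precision; a path ending in `.gz` is gzip-compressed.
#' Re-parsing the file with [parse_pdb_file()] reproduces the structure
#' entity-for-entity.
#'
#' @param structure a [gsp_structure()].
#' @param path output path (`*.pdb`, `*.ent`, optionally `.gz`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- character()
  cls <- toupper(structure$classification)
  lines <- c(lines, sprintf("HEADER    %-40s%9s   %4s",
                            substr(cls, 1, 40), "01-JAN-00",
                            structure$pdb_id))
  if (nzchar(structure$organism))
    lines <- c(lines, sprintf("SOURCE    ORGANISM_SCIENTIFIC: %s;",
                              toupper(structure$organism)))
  serial <- 0L
  ch <- substr(structure$chain_id, 1, 1)
  for (r in structure$residues) {
    for (q in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      nm <- if (q == 1L) "CA" else paste0("C", q)
      lines <- c(lines, pdb_atom_line(
        "ATOM", serial, nm, r$code3, ch, r$seq_index,
        c(r$atoms$x[q], r$atoms$y[q], r$atoms$z[q]), r$atoms$element[q]))
    }
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                            structure$residues[[length(structure$residues)]]$code3,
                            ch, length(structure$residues)))
  hres <- 9000L
  for (l in structure$ligands) {
    hres <- hres + 1L
    for (q in seq_len(nrow(l$atoms))) {
      serial <- serial + 1L
      nm <- substr(paste0(l$code3, q), 1, 4)
      lines <- c(lines, pdb_atom_line(
        "HETATM", serial, nm, l$code3, ch, hres,
        c(l$atoms$x[q], l$atoms$y[q], l$atoms$z[q]), l$atoms$element[q]))
    }
  }
  lines <- c(lines, "END")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
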