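# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain double loops and exhaustive enumeration
# over all injective assignments, vectorized only over the assignment grid.

oracle_min_dist <- function(atoms_a, atoms_b) {
  A <- as.matrix(atoms_a[, c("x", "y", "z")])
  B <- as.matrix(atoms_b[, c("x", "y", "z")])
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

oracle_contacts <- function(st, cutoff = 7.0) {
  res <- st$residues
  n <- length(res)
  rows <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- oracle_min_dist(res[[i]]$atoms, res[[j]]$atoms)
    if (d <= cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "amino_amino", a_id = res[[i]]$amino_id,
        b_id = res[[j]]$amino_id, seq_a = i, seq_b = j, distance = d,
        stringsAsFactors = FALSE)
  }
  for (l in seq_along(st$ligands)) for (j in seq_len(n)) {
    d <- oracle_min_dist(st$ligands[[l]]$atoms, res[[j]]$atoms)
    if (d <= cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "ligand_amino", a_id = st$ligands[[l]]$ligand_id,
        b_id = res[[j]]$amino_id, seq_a = NA_integer_, seq_b = j,
        distance = d, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

sort_hits <- function(df) {
  if (nrow(df) == 0) { rownames(df) <- NULL; return(df) }
  keys <- df[, c("pdb_id", grep("^node\\.", names(df), value = TRUE)),
             drop = FALSE]
  out <- df[do.call(order, unname(as.list(keys))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive enumeration over every injective node -> entity assignment;
# the grid is filtered by vectorized per-edge checks
oracle_search <- function(pattern, structures, cutoff = 7.0) {
  nids <- vapply(pattern$nodes, function(n) n$id, "")
  kinds <- vapply(pattern$nodes, function(n) n$kind, "")
  amino_node <- kinds %in% c("amino", "any_amino")
  all_rows <- list()
  for (st in structures) {
    res <- st$residues; ligs <- st$ligands
    n <- length(res)
    dmat <- matrix(Inf, n, n)
    if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- oracle_min_dist(res[[i]]$atoms, res[[j]]$atoms)
      dmat[i, j] <- dmat[j, i] <- d
    }
    lmat <- if (length(ligs))
      matrix(Inf, length(ligs), n) else matrix(Inf, 0, n)
    for (l in seq_along(ligs)) for (j in seq_len(n))
      lmat[l, j] <- oracle_min_dist(ligs[[l]]$atoms, res[[j]]$atoms)

    pol <- gsp4r::polarity_classes
    cand <- lapply(pattern$nodes, function(nd) {
      if (nd$kind == "amino") {
        which(vapply(res, function(r) r$code3 == nd$name, TRUE))
      } else if (nd$kind == "any_amino") {
        if (!is.null(nd$allowed)) {
          which(vapply(res, function(r) r$code3 %in% nd$allowed, TRUE))
        } else if (is.null(nd$polarity) || nd$polarity == "any") {
          seq_len(n)
        } else {
          which(vapply(res, function(r)
            r$std_name %in% pol[[nd$polarity]], TRUE))
        }
      } else if (nd$kind == "ligand") {
        which(vapply(ligs, function(l) l$code3 == nd$code, TRUE))
      } else seq_along(ligs)
    })
    if (any(vapply(cand, length, 0L) == 0L)) next
    grid <- as.matrix(do.call(expand.grid, cand))
    colnames(grid) <- nids
    keep <- rep(TRUE, nrow(grid))
    ai <- which(amino_node)
    if (length(ai) > 1)
      for (x in seq_along(ai)[-length(ai)]) for (y in (x + 1):length(ai))
        keep <- keep & grid[, ai[x]] != grid[, ai[y]]
    for (e in pattern$edges) {
      ia <- match(e$a, nids); ib <- match(e$b, nids)
      if (e$kind == "distance") {
        d <- if (amino_node[ia] && amino_node[ib]) {
          dmat[cbind(grid[, ia], grid[, ib])]
        } else if (!amino_node[ia]) {
          lmat[cbind(grid[, ia], grid[, ib])]
        } else lmat[cbind(grid[, ib], grid[, ia])]
        keep <- keep & d <= cutoff & d >= e$min & d <= e$max
      } else if (e$kind == "next") {
        keep <- keep & (grid[, ib] == grid[, ia] + 1L)
      } else {
        g <- grid[, ib] - grid[, ia] - 1L
        keep <- keep & g >= e$min & (is.infinite(e$max) | g <= e$max)
      }
    }
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) == 0) next
    for (r in seq_len(nrow(grid))) {
      row <- list(pdb_id = st$pdb_id)
      for (i in seq_along(nids)) {
        row[[paste0("node.", nids[i])]] <- if (amino_node[i])
          res[[grid[r, i]]]$amino_id else ligs[[grid[r, i]]]$ligand_id
      }
      for (e in pattern$edges) {
        ia <- match(e$a, nids); ib <- match(e$b, nids)
        if (e$kind == "distance") {
          row[[paste0("dist.", e$id)]] <-
            if (amino_node[ia] && amino_node[ib]) {
              dmat[grid[r, ia], grid[r, ib]]
            } else if (!amino_node[ia]) {
              lmat[grid[r, ia], grid[r, ib]]
            } else lmat[grid[r, ib], grid[r, ia]]
        } else if (e$kind == "gap") {
          row[[paste0("gap.", e$id)]] <-
            as.integer(grid[r, ib] - grid[r, ia] - 1L)
        }
      }
      all_rows[[length(all_rows) + 1]] <- row
    }
  }
  cols <- c("pdb_id", paste0("node.", nids),
            unlist(lapply(pattern$edges, function(e) {
              if (e$kind == "distance") paste0("dist.", e$id)
              else if (e$kind == "gap") paste0("gap.", e$id)
              else character()
            })))
  if (!length(all_rows)) {
    df <- as.data.frame(setNames(
      lapply(cols, function(cn) {
        if (startsWith(cn, "dist.")) numeric()
        else if (startsWith(cn, "gap.")) integer() else character()
      }), cols), stringsAsFactors = FALSE, check.names = FALSE)
    return(df)
  }
  df <- do.call(rbind, lapply(all_rows, function(r)
    as.data.frame(r[cols], stringsAsFactors = FALSE, check.names = FALSE)))
  names(df) <- cols
  sort_hits(df)
}
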