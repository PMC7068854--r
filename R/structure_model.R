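# Domain types for parsed structures and the contact / sequence relations
# shared by the in-memory matcher and the SQL backend.

#' The 20 standard amino acids grouped by side-chain polarity
#'
#' Classification used by wildcard amino-acid nodes: `non-polar`,
#' `polar uncharged`, `positively charged`, `negatively charged`.
#' Residues outside the 20 standard names carry the standard name
#' `"undefined"` and belong to no polarity class.
#'
#' @format Named list of character vectors of 3-letter residue codes.
#' @export
polarity_classes <- list(
  "non-polar"          = c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
                           "MET", "TRP"),
  "polar uncharged"    = c("SER", "THR", "CYS", "TYR", "ASN", "GLN"),
  "positively charged" = c("LYS", "ARG", "HIS"),
  "negatively charged" = c("ASP", "GLU")
)

#' @rdname polarity_classes
#' @export
standard_amino_names <- unname(unlist(polarity_classes))

# residue codes treated as water, never as ligands
water_codes <- c("HOH", "DOD", "WAT")

# common chemically modified residues that occur inside the polymer as
# HETATM records; they are residues, not ligands.  MSE (selenomethionine)
# is the one with an uncontroversial standard parent.
modified_residue_map <- c(
  MSE = "MET", CSO = "undefined", SEP = "undefined", TPO = "undefined",
  PTR = "undefined", HYP = "undefined", MLY = "undefined", CME = "undefined",
  KCX = "undefined", PCA = "undefined", SEC = "undefined", PYL = "undefined"
)

std_name_for <- function(code3) {
  ifelse(code3 %in% standard_amino_names, code3,
         ifelse(code3 %in% names(modified_residue_map),
                unname(modified_residue_map[code3]), "undefined"))
}

#' Construct an atom table
#'
#' Atoms are stored as a data.frame, one row per atom, because distance
#' computations need coordinate matrices rather than individual records.
#'
#' @param atom_id provenance ids (`"<pdb>_<chain>_<seq>_<ordinal>"`).
#' @param element chemical element symbols.
#' @param serial positive integer atom serial numbers.
#' @param xyz numeric matrix with 3 columns (Angstroms).
#' @return data.frame with columns `atom_id`, `element`, `serial`,
#'   `x`, `y`, `z`.
#' @export
gsp_atoms <- function(atom_id, element, serial, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(atom_id) == nrow(xyz), all(is.finite(xyz)),
            all(serial >= 1))
  data.frame(atom_id = as.character(atom_id),
             element = as.character(element),
             serial = as.integer(serial),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Construct a residue
#'
#' @param amino_id provenance id (`"<pdb>_<chain>_<seq_index>"`).
#' @param seq_index 1-based position in the selected chain.
#' @param code3 3-letter residue code (uppercased).
#' @param atoms atom table as built by [gsp_atoms()]; must be non-empty.
#' @param std_name one of the 20 standard residue names or `"undefined"`;
#'   derived from `code3` when missing.
#' @export
gsp_residue <- function(amino_id, seq_index, code3, atoms, std_name = NULL) {
  code3 <- toupper(code3)
  if (is.null(std_name)) std_name <- std_name_for(code3)
  if (nrow(atoms) == 0L) stop("residue ", amino_id, " has no atoms")
  structure(list(amino_id = amino_id, seq_index = as.integer(seq_index),
                 code3 = code3, std_name = std_name, atoms = atoms),
            class = "gsp_residue")
}

#' Construct a ligand group
#'
#' A ligand is a non-water hetero compound; waters are rejected.
#'
#' @param ligand_id provenance id (`"<pdb>_<chain>_L<ordinal>"`).
#' @param code3 hetero-compound 3-letter code.
#' @param atoms atom table; must be non-empty.
#' @export
gsp_ligand <- function(ligand_id, code3, atoms) {
  code3 <- toupper(code3)
  if (code3 %in% water_codes) stop("water group ", code3, " is not a ligand")
  if (nrow(atoms) == 0L) stop("ligand ", ligand_id, " has no atoms")
  structure(list(ligand_id = ligand_id, code3 = code3, atoms = atoms),
            class = "gsp_ligand")
}

#' Construct a single-chain structure record
#'
#' Represents one PDB entry reduced to its selected chain: an ordered list
#' of residues (seq_index consecutive from 1), the non-water hetero groups
#' assigned to that chain, and header metadata.
#'
#' @param pdb_id 4-character PDB code.
#' @param chain_id author chain identifier.
#' @param residues list of [gsp_residue()] objects ordered by `seq_index`.
#' @param ligands list of [gsp_ligand()] objects (may be empty).
#' @param classification,organism free-text header fields (may be `""`).
#' @param cath_codes optional character vector of dotted CATH codes.
#' @return object of class `gsp_structure`.
#' @export
gsp_structure <- function(pdb_id, chain_id, residues, ligands = list(),
                          classification = "", organism = "",
                          cath_codes = NULL) {
  if (length(residues) == 0L) stop("structure has no residues")
  idx <- vapply(residues, function(r) r$seq_index, integer(1))
  if (!identical(idx, seq_along(residues)))
    stop("residues must be ordered with seq_index consecutive from 1")
  structure(list(pdb_id = pdb_id, chain_id = chain_id,
                 residues = residues, ligands = ligands,
                 classification = classification, organism = organism,
                 cath_codes = cath_codes),
            class = "gsp_structure")
}

#' @export
print.gsp_structure <- function(x, ...) {
  cat(sprintf("<gsp_structure> %s chain %s: %d residues, %d ligand(s)%s\n",
              x$pdb_id, x$chain_id, length(x$residues), length(x$ligands),
              if (nzchar(x$classification))
                paste0(" [", x$classification, "]") else ""))
  invisible(x)
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Minimum atom-pair distance between two atom sets
#'
#' The contact distance between two residues (or a ligand and a residue) is
#' defined as the minimum over all cross pairs of atoms of the Euclidean
#' distance, in Angstroms.
#'
#' @param atoms_a,atoms_b non-empty atom tables ([gsp_atoms()]) or plain
#'   numeric matrices with 3 columns.
#' @return single numeric, Angstroms.  Symmetric in its arguments.
#' @export
min_pair_distance <- function(atoms_a, atoms_b) {
  A <- if (is.matrix(atoms_a)) atoms_a else atom_xyz(atoms_a)
  B <- if (is.matrix(atoms_b)) atoms_b else atom_xyz(atoms_b)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("min_pair_distance: empty atom set")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("min_pair_distance: non-finite coordinates")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  sqrt(max(min(d2), 0))
}

#' Pre-compute contact records for a structure
#'
#' Enumerates every residue pair and every ligand-residue pair whose minimum
#' atom-pair distance does not exceed `cutoff` (default 7.0 A; larger
#' distances are taken to mean no interaction).  Residue pairs are stored
#' once per unordered pair, lower `seq_index` first.
#'
#' A centroid-radius bound prunes pairs that cannot be within the cutoff
#' before the exact cross-pair minimum is computed.
#'
#' @param structure a [gsp_structure()].
#' @param cutoff positive distance cutoff in Angstroms.
#' @return data.frame with columns `kind` (`"amino_amino"` or
#'   `"ligand_amino"`), `a_id`, `b_id`, `seq_a`, `seq_b` (`NA` for the
#'   ligand side), and `distance`.
#' @export
build_contacts <- function(structure, cutoff = 7.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number")
  res <- structure$residues
  ligs <- structure$ligands
  n <- length(res)
  xyz <- lapply(res, function(r) atom_xyz(r$atoms))
  cen <- t(vapply(xyz, colMeans, numeric(3)))
  rad <- vapply(xyz, function(m) {
    sqrt(max(rowSums((m - rep(colMeans(m), each = nrow(m)))^2)))
  }, numeric(1))

  rows <- list()
  if (n >= 2L) {
    cend <- as.matrix(stats::dist(cen))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (cend[i, j] - rad[i] - rad[j] > cutoff) next
        d <- min_pair_distance(xyz[[i]], xyz[[j]])
        if (d <= cutoff) {
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "amino_amino",
            a_id = res[[i]]$amino_id, b_id = res[[j]]$amino_id,
            seq_a = i, seq_b = j, distance = d,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (li in seq_along(ligs)) {
    lx <- atom_xyz(ligs[[li]]$atoms)
    lcen <- colMeans(lx)
    lrad <- sqrt(max(rowSums((lx - rep(lcen, each = nrow(lx)))^2)))
    for (j in seq_len(n)) {
      if (sqrt(sum((lcen - cen[j, ])^2)) - lrad - rad[j] > cutoff) next
      d <- min_pair_distance(lx, xyz[[j]])
      if (d <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "ligand_amino",
          a_id = ligs[[li]]$ligand_id, b_id = res[[j]]$amino_id,
          seq_a = NA_integer_, seq_b = j, distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(kind = character(), a_id = character(),
                      b_id = character(), seq_a = integer(),
                      seq_b = integer(), distance = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Sequence-adjacency pairs of a chain
#'
#' One ordered pair of amino ids per consecutive `seq_index` pair
#' (i, i + 1); a chain of n residues yields n - 1 pairs.
#'
#' @param structure a [gsp_structure()].
#' @return data.frame with columns `a_id`, `b_id`, `seq_a`, `seq_b`.
#' @export
next_pairs <- function(structure) {
  res <- structure$residues
  n <- length(res)
  if (n < 2L)
    return(data.frame(a_id = character(), b_id = character(),
                      seq_a = integer(), seq_b = integer(),
                      stringsAsFactors = FALSE))
  ids <- vapply(res, function(r) r$amino_id, character(1))
  data.frame(a_id = ids[-n], b_id = ids[-1L],
             seq_a = seq_len(n - 1L), seq_b = 2:n,
             stringsAsFactors = FALSE)
}
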