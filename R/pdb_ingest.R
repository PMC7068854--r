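# Parse PDB coordinate files into gsp_structure records: entity extraction,
# largest-chain selection, and provenance id construction.  Coordinate
# records go through bio3d::read.pdb; HEADER/SOURCE metadata lines are
# scanned directly since bio3d does not surface them.

#' Build provenance identifiers
#'
#' Ids encode their own provenance: `"1B38_A_1"` is amino acid number 1 of
#' chain A in entry 1B38, `"1B38_A_1_4"` its atom number 4, and
#' `"1B38_A_L1"` the first ligand group of that chain.
#'
#' @param pdb_id 4-character PDB code.
#' @param chain_id chain identifier.
#' @param seq_index 1-based residue position (amino/atom ids).
#' @param atom_ordinal 1-based atom position within the residue or ligand.
#' @param ligand_ordinal 1-based ligand group ordinal.
#' @return a single id string.
#' @export
make_ids <- function(pdb_id, chain_id, seq_index = NULL,
                     atom_ordinal = NULL, ligand_ordinal = NULL) {
  base <- paste0(toupper(pdb_id), "_", chain_id)
  if (!is.null(ligand_ordinal)) {
    lid <- paste0(base, "_L", ligand_ordinal)
    if (!is.null(atom_ordinal)) return(paste0(lid, "_", atom_ordinal))
    return(lid)
  }
  if (!is.null(seq_index)) {
    aid <- paste0(base, "_", seq_index)
    if (!is.null(atom_ordinal)) return(paste0(aid, "_", atom_ordinal))
    return(aid)
  }
  base
}

#' Select the chain to process
#'
#' Only the chain with the largest number of amino acids is processed;
#' ties break to the lexicographically smallest chain id so that parsing
#' is deterministic.
#'
#' @param chains data.frame with columns `chain_id` and `n_amino`, or a
#'   named integer vector of amino counts.
#' @return the selected chain id.
#' @export
select_chain <- function(chains) {
  if (is.numeric(chains) && !is.null(names(chains)))
    chains <- data.frame(chain_id = names(chains), n_amino = unname(chains),
                         stringsAsFactors = FALSE)
  chains <- chains[chains$n_amino >= 1L, , drop = FALSE]
  if (nrow(chains) == 0L)
    stop("empty-structure: no chain contains amino acids")
  chains <- chains[order(-chains$n_amino, chains$chain_id), , drop = FALSE]
  chains$chain_id[1]
}

# metadata scan: HEADER classification (cols 11-50) and id (63-66),
# SOURCE ORGANISM_SCIENTIFIC
scan_pdb_header <- function(lines) {
  out <- list(pdb_id = "", classification = "", organism = "")
  h <- lines[startsWith(lines, "HEADER")]
  if (length(h)) {
    out$classification <- trimws(substr(h[1], 11, 50))
    out$pdb_id <- trimws(substr(h[1], 63, 66))
  }
  src <- lines[startsWith(lines, "SOURCE")]
  m <- regmatches(src, regexpr("ORGANISM_SCIENTIFIC:\\s*[^;]+", src))
  if (length(m))
    out$organism <- trimws(sub("ORGANISM_SCIENTIFIC:\\s*", "", m[1]))
  out
}

gunzip_to_temp <- function(path) {
  tmp <- tempfile(fileext = ".pdb")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  writeLines(readLines(con, warn = FALSE), tmp)
  tmp
}

#' Parse a PDB coordinate file into a single-chain structure record
#'
#' Reads a `*.pdb` / `*.ent` file (optionally gzipped), keeps the first
#' model and the first-listed alternate location of each atom, selects the
#' amino-acid-richest chain ([select_chain()]), and returns it as a
#' [gsp_structure()].  Modified residues recorded as HETATM inside the
#' polymer (MSE and friends) are kept as residues with standard name
#' `"undefined"` (MSE maps to MET); waters are dropped; remaining hetero
#' groups on the selected chain become ligands.
#'
#' @param path path to the file.
#' @return a [gsp_structure()].
#' @export
parse_pdb_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  real <- if (grepl("\\.gz$", path)) gunzip_to_temp(path) else path
  lines <- readLines(real, warn = FALSE, n = 2000L)
  meta <- scan_pdb_header(lines)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(real, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("parse error in ", basename(path), ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("parse error in ", basename(path), ": no coordinate records")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  # first-listed alternate location per (chain, residue, atom name)
  at$alt[is.na(at$alt)] <- ""
  keep <- !duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                            at$elety, sep = "\r"))
  at <- at[keep, , drop = FALSE]

  pdb_id <- if (nzchar(meta$pdb_id)) toupper(meta$pdb_id) else {
    b <- sub("\\.gz$", "", basename(path))
    b <- tools::file_path_sans_ext(b)
    toupper(sub("^pdb", "", b))
  }

  is_amino <- at$resid %in% standard_amino_names |
    at$resid %in% names(modified_residue_map)
  amino_at <- at[is_amino, , drop = FALSE]
  if (nrow(amino_at) == 0L)
    stop("empty-structure: ", basename(path), " contains no amino acids")
  reskey <- paste(amino_at$chain, amino_at$resno, amino_at$insert, sep = "\r")
  counts <- tapply(reskey, amino_at$chain, function(k) length(unique(k)))
  chain <- select_chain(stats::setNames(as.integer(counts), names(counts)))

  ca <- amino_at[amino_at$chain == chain, , drop = FALSE]
  rk <- paste(ca$resno, ca$insert, sep = "\r")
  uniq <- unique(rk)   # order of appearance -> seq_index
  residues <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    rows <- ca[rk == uniq[i], , drop = FALSE]
    code3 <- toupper(rows$resid[1])
    elem <- ifelse(nzchar(trimws(rows$elesy)), trimws(rows$elesy),
                   substr(trimws(rows$elety), 1, 1))
    atoms <- gsp_atoms(
      atom_id = make_ids(pdb_id, chain, seq_index = i,
                         atom_ordinal = seq_len(nrow(rows))),
      element = elem, serial = rows$eleno,
      xyz = cbind(rows$x, rows$y, rows$z))
    residues[[i]] <- gsp_residue(make_ids(pdb_id, chain, seq_index = i),
                                 i, code3, atoms)
  }

  het <- at[!is_amino & at$chain == chain &
              !(at$resid %in% water_codes), , drop = FALSE]
  ligands <- list()
  if (nrow(het)) {
    lk <- paste(het$resid, het$resno, het$insert, sep = "\r")
    for (grp in unique(lk)) {
      rows <- het[lk == grp, , drop = FALSE]
      ord <- length(ligands) + 1L
      elem <- ifelse(nzchar(trimws(rows$elesy)), trimws(rows$elesy),
                     substr(trimws(rows$elety), 1, 1))
      atoms <- gsp_atoms(
        atom_id = make_ids(pdb_id, chain, ligand_ordinal = ord,
                           atom_ordinal = seq_len(nrow(rows))),
        element = elem, serial = rows$eleno,
        xyz = cbind(rows$x, rows$y, rows$z))
      ligands[[ord]] <- gsp_ligand(make_ids(pdb_id, chain,
                                            ligand_ordinal = ord),
                                   toupper(rows$resid[1]), atoms)
    }
  }

  gsp_structure(pdb_id, chain, residues, ligands,
                classification = meta$classification,
                organism = meta$organism)
}

#' Discover and ingest PDB files from a directory
#'
#' Recursively finds `*.pdb`, `*.ent` and gzipped variants, parses each
#' into a structure, and (when a database is given) loads structure,
#' contacts and adjacency rows, skipping entries already present.
#'
#' @param path directory or character vector of files.
#' @param db optional database handle from [gsp_db_connect()]; when
#'   `NULL`, structures are only parsed.
#' @param ids optional character vector restricting ingestion to these
#'   PDB ids (case-insensitive).
#' @param cutoff contact cutoff in Angstroms.
#' @return an ingest report: list with `files_seen`, `files_parsed`,
#'   `files_skipped`, a per-file data.frame `report`, and (when `db` is
#'   `NULL`) the parsed `structures`.
#' @export
ingest_directory <- function(path, db = NULL, ids = NULL, cutoff = 7.0) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.(pdb|ent)(\\.gz)?$", recursive = TRUE,
               full.names = TRUE)
  } else {
    if (!all(file.exists(path))) stop("no such path: ",
                                      path[!file.exists(path)][1])
    path
  }
  files <- sort(files)
  rep_rows <- list()
  structures <- list()
  for (f in files) {
    entry <- list(file = f, pdb_id = NA_character_, chain = NA_character_,
                  status = "parsed", reason = "")
    parsed <- tryCatch(parse_pdb_file(f), error = function(e) e)
    if (inherits(parsed, "error")) {
      entry$status <- "skipped"; entry$reason <- conditionMessage(parsed)
    } else {
      entry$pdb_id <- parsed$pdb_id; entry$chain <- parsed$chain_id
      if (!is.null(ids) && !tolower(parsed$pdb_id) %in% tolower(ids)) {
        entry$status <- "skipped"; entry$reason <- "not in requested id list"
      } else if (!is.null(db)) {
        n <- gsp_db_load(db, parsed, cutoff = cutoff)
        if (identical(n$skipped, TRUE)) {
          entry$status <- "skipped"; entry$reason <- "already loaded"
        }
      } else {
        structures[[length(structures) + 1L]] <- parsed
      }
    }
    rep_rows[[length(rep_rows) + 1L]] <-
      as.data.frame(entry, stringsAsFactors = FALSE)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(file = character(), pdb_id = character(),
               chain = character(), status = character(),
               reason = character(), stringsAsFactors = FALSE)
  out <- list(files_seen = length(files),
              files_parsed = sum(report$status == "parsed"),
              files_skipped = sum(report$status == "skipped"),
              report = report)
  if (is.null(db)) out$structures <- structures
  out
}
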