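# Structure I/O: read PDB files into a normalized residue model with
# side-chain geometric centers; write per-pattern PDB excerpts; fetch by ID.

#' Parse a PDB file into a residue model
#'
#' Reads a PDB file (via \pkg{bio3d}) and reduces it to the residue-level
#' model all downstream geometry works on: one record per standard
#' amino-acid residue of model 1, each with the geometric center of its
#' side-chain heavy atoms.
#'
#' Filtering rules: only the first model of a multi-model file is used;
#' for alternate locations the first-listed conformer of each atom is kept;
#' waters and non-polymer heteroatom residues are dropped (the method is
#' ligand-independent); MSE and other modified residues with a standard
#' parent are mapped to that parent, unmappable residues are skipped with
#' a warning.
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain identifiers to keep
#'   (default: all protein chains).
#' @param id structure identifier recorded in the model; defaults to the
#'   file stem.
#' @return an object of class `structure_model`: a list with `id`,
#'   `residues` (data frame with chain, resno, insert, resid, aa1, label,
#'   x, y, z), `atoms` (the retained atom records, for excerpt writing)
#'   and `source_path`.
#' @seealso [side_chain_center()], [build_grid()]
#' @export
parse_structure <- function(path, chains = NULL, id = NULL) {
  if (!file.exists(path) || dir.exists(path)) {
    stop("cannot read PDB file: ", path)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  atoms <- pdb$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "

  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  atoms <- atoms[!(atoms$resid %in% WATER_NAMES), , drop = FALSE]

  # map modified residues to their standard parent, then keep standard only
  mapped <- atoms$resid %in% names(MODIFIED_PARENT)
  atoms$resid[mapped] <- MODIFIED_PARENT[atoms$resid[mapped]]
  standard <- atoms$resid %in% names(AA_321)
  nonstd <- atoms$type == "ATOM" & !standard
  if (any(nonstd)) {
    skipped <- unique(atoms$resid[nonstd])
    warning("skipping residues with no standard parent: ",
            paste(skipped, collapse = ", "))
  }
  atoms <- atoms[standard, , drop = FALSE]

  if (nrow(atoms) == 0) stop("no amino-acid residues in ", path)

  # first-listed conformer per (chain, resno, insert, atom name)
  akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  atoms <- atoms[!duplicated(akey), , drop = FALSE]

  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  first_seen <- !duplicated(rkey)
  res_order <- rkey[first_seen]

  centers <- matrix(NA_real_, length(res_order), 3)
  keep <- logical(length(res_order))
  info <- atoms[first_seen, c("chain", "resno", "insert", "resid")]
  for (k in seq_along(res_order)) {
    rec <- atoms[rkey == res_order[k], , drop = FALSE]
    ctr <- tryCatch(side_chain_center(rec), error = function(e) NULL)
    if (is.null(ctr)) next
    centers[k, ] <- ctr
    keep[k] <- TRUE
  }
  if (any(!keep)) {
    warning("dropped ", sum(!keep), " residue(s) with no usable atoms")
  }
  info <- info[keep, , drop = FALSE]
  centers <- centers[keep, , drop = FALSE]
  if (nrow(info) == 0) stop("no amino-acid residues in ", path)

  residues <- data.frame(
    chain = info$chain,
    resno = info$resno,
    insert = info$insert,
    resid = info$resid,
    aa1 = unname(AA_321[info$resid]),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    stringsAsFactors = FALSE
  )
  residues$label <- sprintf("%s%d%s.%s", residues$resid, residues$resno,
                            residues$insert, residues$chain)
  rownames(residues) <- NULL

  structure(
    list(id = id, residues = residues, atoms = atoms, source_path = path),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model", x$id, "-", nrow(x$residues), "residues,",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' Geometric center of a residue's side chain
#'
#' Returns the unweighted mean coordinate of the side-chain heavy atoms
#' (all non-hydrogen atoms excluding the backbone N, CA, C, O and OXT).
#' Glycine has no side-chain heavy atom, so its CA coordinate is returned.
#'
#' @param rec data frame of one residue's atom records with columns
#'   `elety`, `x`, `y`, `z` (and optionally `elesy`, the element symbol,
#'   used to drop hydrogens).
#' @return numeric length-3 coordinate (x, y, z) in Angstrom.
#' @export
side_chain_center <- function(rec) {
  if (nrow(rec) == 0) stop("residue has no atoms")
  if (!is.null(rec$elesy)) {
    rec <- rec[!(rec$elesy %in% c("H", "D")), , drop = FALSE]
  }
  rec <- rec[!grepl("^[0-9]*[HD]", rec$elety), , drop = FALSE]
  side <- rec[!(rec$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  if (nrow(side) == 0) {
    side <- rec[rec$elety == "CA", , drop = FALSE]
  }
  if (nrow(side) == 0) stop("residue has no usable atoms")
  c(mean(side$x), mean(side$y), mean(side$z))
}

#' Write the atom records of one pattern to a PDB file
#'
#' Extracts the full atom records of exactly the pattern's residues from
#' the parsed model, preserving original chain identifiers and residue
#' numbering, and writes them as a standalone PDB file.
#'
#' @param pattern a `pattern3d` object from [detect_patterns()].
#' @param model the `structure_model` the pattern was detected in.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_pdb <- function(pattern, model, path) {
  stopifnot(inherits(pattern, "pattern3d"), inherits(model, "structure_model"))
  if (length(pattern$residue_idx) == 0) stop("empty pattern: nothing to write")
  res <- model$residues[pattern$residue_idx, , drop = FALSE]
  atoms <- model$atoms
  akey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  rkey <- paste(res$chain, res$resno, res$insert, sep = "|")
  sel <- atoms[akey %in% rkey, , drop = FALSE]
  if (nrow(sel) == 0) stop("pattern residues not found in model")
  lines <- c(
    sprintf("REMARK   3D pattern %s from %s", pattern$anchor, model$id),
    format_atom_lines(sel),
    "TER", "END"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# fixed-width PDB ATOM/HETATM records from a bio3d-style atom data frame
format_atom_lines <- function(a) {
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  elesy <- if (is.null(a$elesy)) substr(trimws(a$elety), 1, 1) else a$elesy
  elesy[is.na(elesy)] <- ""
  occ <- if (is.null(a$o)) rep(1, nrow(a)) else ifelse(is.na(a$o), 1, a$o)
  bfac <- if (is.null(a$b)) rep(0, nrow(a)) else ifelse(is.na(a$b), 0, a$b)
  chain <- ifelse(a$chain == "" | is.na(a$chain), " ", a$chain)
  ins <- ifelse(is.na(a$insert) | a$insert == "", " ", a$insert)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$type, a$eleno %% 100000, name4, " ", a$resid, chain,
          a$resno, ins, a$x, a$y, a$z, occ, bfac, elesy)
}

#' Fetch a structure from the Protein Data Bank
#'
#' Downloads the PDB entry once into `cache_dir`; subsequent calls return
#' the cached file without touching the network. IDs are normalized to
#' upper case, so "2o3p" and "2O3P" share a cache entry.
#'
#' @param pdb_id 4-character PDB identifier.
#' @param cache_dir directory used as download cache.
#' @return local path to the cached PDB file.
#' @export
fetch_structure <- function(pdb_id, cache_dir = tools::R_user_dir("patternsim", "cache")) {
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id)) {
    stop("malformed PDB ID: '", pdb_id, "' (expected 4 characters, digit first)")
  }
  pdb_id <- toupper(pdb_id)
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(pdb_id, ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", pdb_id, ".pdb")
  ok <- tryCatch(
    download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("failed to fetch PDB entry ", pdb_id, " from ", url)
  }
  dest
}
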