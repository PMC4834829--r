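# Synthetic PDB generation with exactly planted side-chain centers, so
# every pipeline stage is testable without downloads. Residues are built
# with a single CB side-chain atom placed on the requested center (CA for
# glycine), which makes the planted geometry exactly recoverable; no
# attempt is made to mimic real rotamers or backbone plausibility.

#' Generate a synthetic PDB structure with planted side-chain centers
#'
#' Emits minimal but standard-conformant PDB ATOM records realizing each
#' requested residue with a side chain whose heavy-atom center equals the
#' planted coordinate exactly (single-CB construction; glycine is realized
#' by placing CA on the center). Optional decoys exercise the parser's
#' filtering rules.
#'
#' @param spec data frame with columns `chain`, `resno`, `aa3`
#'   (three-letter residue name), `x`, `y`, `z` (planted side-chain center
#'   in Angstrom); optional `insert`.
#' @param waters number of water (HOH) decoy molecules to append.
#' @param altloc_decoy if `TRUE`, the first non-glycine residue gets an
#'   extra altloc-B CB displaced by (5, 5, 5); the altloc-A CB stays on
#'   the planted center.
#' @param extra_model if `TRUE`, wraps the records in MODEL 1 and appends
#'   a MODEL 2 copy shifted by 50 Angstrom (which parsers must ignore).
#' @param het_decoy if `TRUE`, appends a HETATM ligand (LIG) record.
#' @param path if given, the text is written there and `path` is returned;
#'   otherwise the lines are returned as a character vector.
#' @return `path` (if given) or the PDB text lines.
#' @export
make_structure <- function(spec, waters = 0, altloc_decoy = FALSE,
                           extra_model = FALSE, het_decoy = FALSE,
                           path = NULL) {
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  needed <- c("chain", "resno", "aa3", "x", "y", "z")
  if (!all(needed %in% names(spec))) {
    stop("spec needs columns: ", paste(needed, collapse = ", "))
  }
  if (is.null(spec$insert)) spec$insert <- ""
  key <- paste(spec$chain, spec$resno, spec$insert)
  if (anyDuplicated(key)) stop("duplicate residue identity in spec")
  bad <- setdiff(unique(spec$aa3), names(AA_321))
  if (length(bad) > 0) stop("non-standard residue name(s): ",
                            paste(bad, collapse = ", "))

  serial <- 0L
  atom_line <- function(type, name, alt, resid, chain, resno, icode,
                        xyz, occ = 1) {
    serial <<- serial + 1L
    name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name4, alt, resid, chain, resno,
            if (icode == "") " " else icode,
            xyz[1], xyz[2], xyz[3], occ, 0,
            substr(trimws(name), 1, 1))
  }

  emit_residues <- function(shift = c(0, 0, 0)) {
    lines <- character(0)
    altloc_used <- FALSE
    for (r in seq_len(nrow(spec))) {
      ctr <- c(spec$x[r], spec$y[r], spec$z[r]) + shift
      resid <- spec$aa3[r]
      ch <- spec$chain[r]
      no <- spec$resno[r]
      ic <- spec$insert[r]
      if (resid == "GLY") {
        # CA carries the planted center; N/C/O are offset backbone dressing
        lines <- c(lines,
          atom_line("ATOM", "N", " ", resid, ch, no, ic, ctr + c(-1.4, 0.6, 0)),
          atom_line("ATOM", "CA", " ", resid, ch, no, ic, ctr),
          atom_line("ATOM", "C", " ", resid, ch, no, ic, ctr + c(1.4, 0.6, 0)),
          atom_line("ATOM", "O", " ", resid, ch, no, ic, ctr + c(1.9, 1.6, 0)))
      } else {
        lines <- c(lines,
          atom_line("ATOM", "N", " ", resid, ch, no, ic, ctr + c(-2.1, 1.1, 0.3)),
          atom_line("ATOM", "CA", " ", resid, ch, no, ic, ctr + c(-0.9, 1.3, -0.2)),
          atom_line("ATOM", "C", " ", resid, ch, no, ic, ctr + c(0.2, 2.2, 0.4)),
          atom_line("ATOM", "O", " ", resid, ch, no, ic, ctr + c(0.2, 3.2, 1.0)))
        if (altloc_decoy && !altloc_used) {
          altloc_used <- TRUE
          lines <- c(lines,
            atom_line("ATOM", "CB", "A", resid, ch, no, ic, ctr, occ = 0.6),
            atom_line("ATOM", "CB", "B", resid, ch, no, ic, ctr + c(5, 5, 5),
                      occ = 0.4))
        } else {
          lines <- c(lines, atom_line("ATOM", "CB", " ", resid, ch, no, ic, ctr))
        }
      }
    }
    lines
  }

  body <- emit_residues()
  body <- c(body, "TER")
  if (waters > 0) {
    for (w in seq_len(waters)) {
      body <- c(body, atom_line("HETATM", "O", " ", "HOH", "W", 1000L + w,
                                "", c(90 + w, 90, 90)))
    }
  }
  if (het_decoy) {
    body <- c(body, atom_line("HETATM", "C1", " ", "LIG", "L", 2000L, "",
                              c(80, 80, 80)))
  }

  lines <- if (extra_model) {
    c("MODEL        1", body, "ENDMDL",
      "MODEL        2", emit_residues(shift = c(50, 0, 0)), "TER", "ENDMDL",
      "END")
  } else {
    c(body, "END")
  }

  if (!is.null(path)) {
    writeLines(lines, path)
    return(path)
  }
  lines
}

# members of each physicochemical category, three-letter names
CATEGORY_MEMBERS <- split(
  names(AA_321)[match(names(SC_CATEGORY), AA_321)],
  unname(SC_CATEGORY)
)

#' Generate a perturbed twin of a synthetic structure
#'
#' Builds structure A from `spec` and structure B as a copy whose planted
#' centers are jittered by isotropic Gaussian noise and in which selected
#' residues are mutated within their physicochemical category (e.g. LEU to
#' VAL), which leaves the sequence-component descriptor unchanged. With
#' zero jitter and zero mutations, B is geometrically identical to A and
#' every pattern of A has a 100-GScore partner in B.
#'
#' @param spec residue specification, see [make_structure()].
#' @param jitter standard deviation (Angstrom) of the coordinate noise.
#' @param n_mutations number of residues to mutate within-category.
#' @param seed integer seed making the perturbation reproducible.
#' @param path_a,path_b optional output paths for the two PDB files.
#' @return list with elements `a` and `b` (paths if given, else text
#'   lines) and `spec_b` (the perturbed specification).
#' @export
make_twin_pair <- function(spec, jitter = 0, n_mutations = 0, seed = NULL,
                           path_a = NULL, path_b = NULL) {
  stopifnot(jitter >= 0, n_mutations >= 0)
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  if (!is.null(seed)) set.seed(seed)
  spec_b <- spec
  n <- nrow(spec)
  if (jitter > 0) {
    spec_b$x <- spec_b$x + rnorm(n, 0, jitter)
    spec_b$y <- spec_b$y + rnorm(n, 0, jitter)
    spec_b$z <- spec_b$z + rnorm(n, 0, jitter)
  }
  if (n_mutations > 0) {
    # mutable residues have a same-category alternative (PRO does not)
    mutable <- which(vapply(spec$aa3, function(r) {
      length(CATEGORY_MEMBERS[[SC_CATEGORY[AA_321[r]]]]) > 1
    }, logical(1)))
    pick <- sample(mutable, min(n_mutations, length(mutable)))
    for (r in pick) {
      cat_members <- CATEGORY_MEMBERS[[SC_CATEGORY[AA_321[spec$aa3[r]]]]]
      alternatives <- setdiff(cat_members, spec$aa3[r])
      spec_b$aa3[r] <- alternatives[sample.int(length(alternatives), 1)]
    }
  }
  list(
    a = make_structure(spec, path = path_a),
    b = make_structure(spec_b, path = path_b),
    spec_b = spec_b
  )
}
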