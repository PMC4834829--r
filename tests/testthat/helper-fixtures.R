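# Shared fixture builders and independent brute-force oracles.

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# residue spec with planted centers; coordinates drawn in a box of given size
random_spec <- function(n, box = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    chain = "A", resno = seq_len(n),
    aa3 = sample(STANDARD_AA3, n, replace = TRUE),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    stringsAsFactors = FALSE
  )
}

fixture_model <- function(spec, ...) {
  path <- tempfile(fileext = ".pdb")
  make_structure(spec, path = path, ...)
  parse_structure(path)
}

# five ASP/PRO/SER/GLU/ARG residues in a compact arrangement (pairwise
# center distances all within [3, 8] A), numbered as requested
five_residue_spec <- function(resnos, chain = "A") {
  data.frame(
    chain = chain, resno = resnos,
    aa3 = c("ASP", "PRO", "SER", "GLU", "ARG"),
    x = c(0.0, 5.0, 2.5, 1.0, 4.0),
    y = c(0.0, 0.0, 4.3, 5.5, 4.8),
    z = c(0.0, 0.0, 0.0, 3.0, 3.5),
    stringsAsFactors = FALSE
  )
}

# ---- independent oracles ------------------------------------------------

# pair count by explicit double loop (grid-size oracle)
brute_pair_count <- function(xyz, gr) {
  n <- nrow(xyz)
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= gr) count <- count + 1L
    }
  }
  count
}

# optimal closed-tour length by enumeration of all permutations
brute_tsp_length <- function(xyz) {
  n <- nrow(xyz)
  D <- as.matrix(dist(xyz))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(2:n)) {
    tour <- c(1, p)
    nxt <- c(tour[-1], 1)
    len <- sum(D[cbind(tour, nxt)])
    best <- min(best, len)
  }
  best
}

# multiset intersection cardinality by element-wise removal
brute_multiset_intersection <- function(a, b) {
  count <- 0L
  for (tok in a) {
    hit <- match(tok, b)
    if (!is.na(hit)) {
      count <- count + 1L
      b <- b[-hit]
    }
  }
  count
}

# GScore of one descriptor pair recomputed from the raw formulas
brute_pair_score <- function(da, db, w = c(25, 25, 25, 25)) {
  ratio <- function(a, b) 100 * brute_multiset_intersection(a, b) /
    max(length(a), length(b))
  e <- if (abs(da$nbe) == 0 && abs(db$nbe) == 0) 100 else
    100 * min(abs(da$nbe), abs(db$nbe)) / max(abs(da$nbe), abs(db$nbe))
  parts <- c(ratio(da$dist, db$dist), e, ratio(da$tsp, db$tsp),
             ratio(da$sc, db$sc))
  list(parts = parts, gscore = sum(parts * w) / 100)
}
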