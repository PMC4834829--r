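# The four per-pattern descriptors: distance-token multiset, summed
# non-bonded energy, sequence-component categories, and the
# travelling-salesman perimeter.

# integer rounding, half away from zero toward +inf (7.5 -> 8), unlike
# base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Distance token for a residue pair
#'
#' Encodes a residue pair and its side-chain-center distance as a token of
#' the form LETTER-INT-LETTER (e.g. "L5R"): the distance is rounded to the
#' nearest integer Angstrom (half up) and the two one-letter codes are
#' placed in lexicographic order around it, so the token is independent of
#' the order the two residues are given in.
#'
#' @param a,b one-letter amino-acid codes.
#' @param d distance in Angstrom (>= 0).
#' @return character vector of tokens.
#' @examples
#' pair_token("R", "L", 5.0)  # "L5R"
#' @export
pair_token <- function(a, b, d) {
  bad <- setdiff(unique(c(a, b)), names(SC_CATEGORY))
  if (length(bad) > 0) {
    stop("unknown one-letter residue code(s): ", paste(bad, collapse = ", "))
  }
  if (any(d < 0)) stop("distances must be non-negative")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste0(lo, round_half_up(d), hi)
}

#' Distance descriptor of a pattern
#'
#' One token per unordered residue pair of the pattern (n(n-1)/2 tokens
#' for n residues), built from side-chain-center distances with
#' [pair_token()]. Duplicate tokens are preserved: the descriptor is a
#' multiset.
#'
#' @param pattern a `pattern3d`.
#' @param model the `structure_model` the pattern belongs to.
#' @return character vector of tokens, length n(n-1)/2.
#' @export
dist_descriptor <- function(pattern, model) {
  res <- model$residues[pattern$residue_idx, , drop = FALSE]
  if (nrow(res) < 2) stop("distance descriptor needs at least 2 residues")
  xyz <- as.matrix(res[, c("x", "y", "z")])
  pr <- which(upper.tri(diag(nrow(res))), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                     xyz[pr[, 2], , drop = FALSE])^2))
  pair_token(res$aa1[pr[, 1]], res$aa1[pr[, 2]], d)
}

#' Non-bonded-energy descriptor of a pattern
#'
#' Sum over the pattern's residues of the tabulated short+medium-range
#' non-bonded energy of each residue type.
#'
#' @param pattern a `pattern3d`.
#' @param model the `structure_model` the pattern belongs to.
#' @param table named numeric energy table, see [default_energy_table()].
#' @return scalar energy (units of the table).
#' @export
nbe_descriptor <- function(pattern, model, table = default_energy_table()) {
  aa <- model$residues$aa1[pattern$residue_idx]
  missing <- setdiff(unique(aa), names(table))
  if (length(missing) > 0) {
    stop("residue(s) missing from energy table: ",
         paste(missing, collapse = ", "))
  }
  sum(table[aa])
}

#' Sequence-component descriptor of a pattern
#'
#' The multiset of physicochemical categories ([residue_category()]) of
#' the pattern's residues; cardinality n, independent of residue order.
#'
#' @inheritParams dist_descriptor
#' @return character vector of category letters, length n.
#' @export
sc_descriptor <- function(pattern, model) {
  residue_category(model$residues$aa1[pattern$residue_idx])
}

#' Solve the travelling-salesman problem on a small point set
#'
#' Returns a closed tour (cyclic visiting order) over the points. For
#' n <= 10 the tour is provably optimal (Held-Karp dynamic programming);
#' for larger n, nearest-neighbour construction followed by 2-opt moves
#' until no improvement remains. Deterministic given input order.
#'
#' @param points numeric matrix, one 3D coordinate per row (>= 3 rows).
#' @return integer vector: the visiting order (a permutation of row
#'   indices); the tour closes from the last index back to the first.
#'   The tour length is attached as attribute `"length"`.
#' @export
solve_tsp <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("a tour needs at least 3 points")
  D <- as.matrix(dist(points))
  tour <- if (n <= 10) tsp_exact(D) else tsp_2opt(D)
  attr(tour, "length") <- tour_length(tour, D)
  tour
}

tour_length <- function(tour, D) {
  nxt <- c(tour[-1], tour[1])
  sum(D[cbind(tour, nxt)])
}

# Held-Karp exact DP over subsets, start fixed at vertex 1
tsp_exact <- function(D) {
  n <- nrow(D)
  m <- n - 1                       # vertices 2..n, bit k-1 <-> vertex k+1
  full <- bitwShiftL(1L, m) - 1L
  cost <- matrix(Inf, full + 1L, m)
  par <- matrix(0L, full + 1L, m)
  for (k in seq_len(m)) cost[bitwShiftL(1L, k - 1L) + 1L, k] <- D[1, k + 1]
  for (s in seq_len(full)) {
    row <- cost[s + 1L, ]
    ends <- which(is.finite(row))
    if (length(ends) == 0) next
    for (k in seq_len(m)) {
      if (bitwAnd(s, bitwShiftL(1L, k - 1L)) != 0L) next
      s2 <- bitwOr(s, bitwShiftL(1L, k - 1L))
      cand <- row[ends] + D[ends + 1L, k + 1L]
      best <- which.min(cand)
      if (cand[best] < cost[s2 + 1L, k]) {
        cost[s2 + 1L, k] <- cand[best]
        par[s2 + 1L, k] <- ends[best]
      }
    }
  }
  closing <- cost[full + 1L, ] + D[2:n, 1]
  k <- which.min(closing)
  tour <- integer(n)
  s <- full
  for (pos in n:2) {
    tour[pos] <- k + 1L
    k_prev <- par[s + 1L, k]
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, k - 1L)))
    k <- k_prev
  }
  tour[1] <- 1L
  tour
}

# nearest-neighbour start + first-improvement 2-opt
tsp_2opt <- function(D) {
  n <- nrow(D)
  tour <- integer(n)
  tour[1] <- 1L
  unvisited <- rep(TRUE, n)
  unvisited[1] <- FALSE
  for (pos in 2:n) {
    cur <- tour[pos - 1]
    cand <- which(unvisited)
    nxt <- cand[which.min(D[cur, cand])]
    tour[pos] <- nxt
    unvisited[nxt] <- FALSE
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- tour[i]; b <- tour[i %% n + 1]
        c_ <- tour[j]; d_ <- tour[j %% n + 1]
        if (a == c_ || b == d_ || a == d_) next
        delta <- (D[a, c_] + D[b, d_]) - (D[a, b] + D[c_, d_])
        if (delta < -1e-12) {
          tour[(i + 1):j] <- rev(tour[(i + 1):j])
          improved <- TRUE
        }
      }
    }
  }
  tour
}

#' Perimeter (travelling-salesman) descriptor of a pattern
#'
#' Solves the TSP on the pattern's side-chain centers and emits one
#' [pair_token()] per tour edge: n tokens for n residues, stored as a
#' multiset so the comparison is independent of tour starting point and
#' direction.
#'
#' @inheritParams dist_descriptor
#' @return character vector of tokens, length n.
#' @export
tsp_descriptor <- function(pattern, model) {
  res <- model$residues[pattern$residue_idx, , drop = FALSE]
  if (nrow(res) < 3) stop("perimeter descriptor needs at least 3 residues")
  xyz <- as.matrix(res[, c("x", "y", "z")])
  tour <- solve_tsp(xyz)
  nxt <- c(tour[-1], tour[1])
  d <- sqrt(rowSums((xyz[tour, , drop = FALSE] - xyz[nxt, , drop = FALSE])^2))
  pair_token(res$aa1[tour], res$aa1[nxt], d)
}

#' Compute all four descriptors for a list of patterns
#'
#' @param patterns list of `pattern3d` from [detect_patterns()].
#' @param model the `structure_model` they belong to.
#' @param energy_table named numeric energy table.
#' @return list of `descriptor_set` objects with elements `dist`, `nbe`,
#'   `sc`, `tsp`, `pattern_ref` (anchor label), `structure_id` and `n`.
#' @export
describe_patterns <- function(patterns, model,
                              energy_table = default_energy_table()) {
  lapply(patterns, function(p) {
    structure(
      list(
        dist = dist_descriptor(p, model),
        nbe = nbe_descriptor(p, model, energy_table),
        sc = sc_descriptor(p, model),
        tsp = tsp_descriptor(p, model),
        pattern_ref = p$anchor,
        structure_id = p$structure_id,
        n = p$n
      ),
      class = "descriptor_set"
    )
  })
}

#' Read a residue energy table
#'
#' Two-column plain text (one-letter code, value); `#` comments allowed.
#' All 20 standard residues must be present with finite values.
#'
#' @param path path to the table file.
#' @return named numeric vector keyed by one-letter code.
#' @export
read_energy_table <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("aa1", "value"),
                    colClasses = c("character", "numeric"))
  values <- tab$value
  names(values) <- tab$aa1
  missing <- setdiff(unname(AA_321), names(values))
  if (length(missing) > 0) {
    stop("energy table lacks residue(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(values))) stop("energy table has non-finite values")
  values
}

.energy_cache <- new.env(parent = emptyenv())

#' Packaged default residue energy table
#'
#' Per-residue short+medium-range non-bonded energies used by the NbE
#' descriptor. The packaged values (inst/extdata/residue_nbe_synthetic.tsv)
#' are a synthetic stand-in scaled by side-chain size and polarizability,
#' not measured reference data; supply your own table via
#' [read_energy_table()] for work where absolute NbE values matter. Note
#' the NbE *similarity* is scale-free for patterns of identical
#' composition (it is then 100 under any table).
#'
#' @return named numeric vector keyed by one-letter code.
#' @export
default_energy_table <- function() {
  if (is.null(.energy_cache$table)) {
    path <- system.file("extdata", "residue_nbe_synthetic.tsv",
                        package = "patternsim", mustWork = TRUE)
    .energy_cache$table <- read_energy_table(path)
  }
  .energy_cache$table
}
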