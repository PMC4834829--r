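# Pattern detection: grow one candidate 3D pattern from each grid point
# under the near/far threshold constraints.

#' Detection parameters
#'
#' Bundles the thresholds bounding a 3D pattern's size. `nt` (near
#' threshold) is the minimum residue-to-anchor distance; `ft` (far
#' threshold) is both the maximum residue-to-anchor distance and the
#' maximum residue-to-residue distance within a pattern. The defaults
#' (nt = 3, ft = 10, min_residues = 3) are this package's own choices,
#' sized for drug-binding-site-like patterns.
#'
#' @param nt near threshold in Angstrom (>= 0).
#' @param ft far threshold in Angstrom (> nt).
#' @param min_residues minimum residues per pattern (>= 3 by default;
#'   a perimeter needs at least 3 vertices).
#' @return a `detection_params` list.
#' @export
detection_params <- function(nt = 3, ft = 10, min_residues = 3) {
  stopifnot(is.numeric(nt), length(nt) == 1, nt >= 0,
            is.numeric(ft), length(ft) == 1, ft > 0,
            min_residues >= 1)
  if (nt >= ft) stop("near threshold must be smaller than far threshold")
  structure(list(nt = nt, ft = ft, min_residues = as.integer(min_residues)),
            class = "detection_params")
}

#' Detect 3D patterns from a virtual grid
#'
#' Grows one candidate pattern per grid point: residues whose side-chain
#' centers lie at anchor distance in `[nt, ft]` form the candidate set,
#' which is then pruned (see [pairwise_prune()]) until all pairwise
#' center distances are at most `ft`. Patterns with fewer than
#' `min_residues` residues are dropped. Output order follows grid order,
#' and each pattern records its anchor's "AtomN" label.
#'
#' @param model a `structure_model`.
#' @param grid a `pattern_grid` built on the same model.
#' @param params a [detection_params()] list.
#' @param dedup if `TRUE`, collapse patterns with identical residue sets
#'   to the first anchor that produced them (default `FALSE`: one pattern
#'   per grid point).
#' @return list of `pattern3d` objects, each with `structure_id`,
#'   `anchor` (grid point label), `anchor_coord`, `residue_idx` (row
#'   indices into `model$residues`) and `n`.
#' @export
detect_patterns <- function(model, grid, params = detection_params(),
                            dedup = FALSE) {
  stopifnot(inherits(model, "structure_model"),
            inherits(grid, "pattern_grid"),
            inherits(params, "detection_params"))
  res <- model$residues
  xyz <- as.matrix(res[, c("x", "y", "z")])
  n <- nrow(xyz)
  D <- as.matrix(dist(xyz))
  out <- vector("list", nrow(grid))
  m <- 0L
  seen <- character(0)
  for (g in seq_len(nrow(grid))) {
    anchor <- c(grid$x[g], grid$y[g], grid$z[g])
    da <- sqrt(colSums((t(xyz) - anchor)^2))
    cand <- which(da >= params$nt & da <= params$ft)
    if (length(cand) >= params$min_residues) {
      keep <- pairwise_prune(cand, D = D, ft = params$ft, anchor_dist = da)
      if (length(keep) >= params$min_residues) {
        if (dedup) {
          key <- paste(keep, collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
        }
        m <- m + 1L
        out[[m]] <- structure(
          list(structure_id = model$id, anchor = grid$atom[g],
               anchor_coord = anchor, residue_idx = keep,
               n = length(keep)),
          class = "pattern3d"
        )
      }
    }
  }
  out[seq_len(m)]
}

#' @export
print.pattern3d <- function(x, ...) {
  cat("pattern3d", x$anchor, "in", x$structure_id, "-", x$n, "residues\n")
  invisible(x)
}

#' Prune candidates until all pairwise distances fit the far threshold
#'
#' Repeatedly removes the candidate participating in the most pairwise
#' violations (center distance > `ft`); ties are broken by larger distance
#' to the anchor, then by later file order. Terminates when no violation
#' remains, so the result is a subset whose pairwise distances are all at
#' most `ft`; feasible inputs are returned unchanged.
#'
#' @param cand integer vector of candidate residue indices.
#' @param D full pairwise distance matrix of the model's side-chain
#'   centers.
#' @param ft far threshold in Angstrom.
#' @param anchor_dist numeric vector of anchor distances (indexed like
#'   `D`), used for tie-breaking.
#' @return integer vector, the retained subset of `cand`.
#' @export
pairwise_prune <- function(cand, D, ft, anchor_dist) {
  while (length(cand) > 1) {
    viol <- rowSums(D[cand, cand, drop = FALSE] > ft)
    if (max(viol) == 0) break
    worst <- which(viol == max(viol))
    if (length(worst) > 1) {
      ad <- anchor_dist[cand[worst]]
      worst <- worst[ad == max(ad)]
      if (length(worst) > 1) worst <- worst[which.max(cand[worst])]
    }
    cand <- cand[-worst]
  }
  cand
}
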