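# Pairwise scoring: the four partial similarities and the weighted GScore
# for every cross-structure pattern pair.

# multiset intersection cardinality: sum over tokens of min(count_a, count_b)
multiset_intersection <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

overlap_similarity <- function(a, b, what) {
  if (length(a) == 0 || length(b) == 0) {
    stop("undefined similarity: empty ", what, " descriptor")
  }
  100 * multiset_intersection(a, b) / max(length(a), length(b))
}

#' Partial similarities of the four descriptors
#'
#' `sdist()`, `stsp()` and `ssc()` are multiset-overlap similarities: the
#' cardinality of the multiset intersection divided by the larger
#' cardinality, times 100. `snbe()` compares the magnitudes of the two
#' summed energies: min(|a|, |b|) / max(|a|, |b|) times 100, defined as
#' 100 when both energies are 0 (identical) and 0 when exactly one is 0.
#'
#' @param a,b token multisets (character vectors) for `sdist`/`stsp`/
#'   `ssc`, or scalar energies for `snbe`.
#' @return similarity percentage in \[0, 100\].
#' @name partial_similarities
NULL

#' @rdname partial_similarities
#' @export
sdist <- function(a, b) overlap_similarity(a, b, "distance")

#' @rdname partial_similarities
#' @export
stsp <- function(a, b) overlap_similarity(a, b, "perimeter")

#' @rdname partial_similarities
#' @export
ssc <- function(a, b) overlap_similarity(a, b, "sequence-component")

#' @rdname partial_similarities
#' @export
snbe <- function(a, b) {
  aa <- abs(a)
  ab <- abs(b)
  if (aa == 0 && ab == 0) return(100)
  100 * min(aa, ab) / max(aa, ab)
}

#' Descriptor weights
#'
#' Relative contributions (in percent) of the distance (`dp`), non-bonded
#' energy (`cp`), perimeter (`tp`) and sequence-component (`sp`) partial
#' similarities to the GScore. They must sum to 100; the default is an
#' equal 25 each.
#'
#' @param dp,cp,tp,sp percentages in \[0, 100\].
#' @return a `score_weights` list.
#' @export
score_weights <- function(dp = 25, cp = 25, tp = 25, sp = 25) {
  w <- c(dp = dp, cp = cp, tp = tp, sp = sp)
  if (any(w < 0 | w > 100)) stop("weights must lie in [0, 100]")
  if (abs(sum(w) - 100) > 1e-9) stop("weights must sum to 100")
  structure(as.list(w), class = "score_weights")
}

#' Combined similarity score of a pattern pair
#'
#' GScore = (SDist * dp + SNbE * cp + STsp * tp + SSc * sp) / 100: the
#' weighted mean of the four partial similarities, itself a percentage in
#' \[0, 100\]. Setting one weight to 100 makes the GScore equal that
#' partial similarity exactly.
#'
#' @param sdist,snbe,stsp,ssc partial similarity percentages.
#' @param weights a [score_weights()] list.
#' @return GScore percentage.
#' @export
gscore <- function(sdist, snbe, stsp, ssc, weights = score_weights()) {
  if (!inherits(weights, "score_weights")) {
    weights <- do.call(score_weights, as.list(weights))
  }
  (sdist * weights$dp + snbe * weights$cp +
     stsp * weights$tp + ssc * weights$sp) / 100
}

#' All-versus-all comparison of two descriptor lists
#'
#' Evaluates every cross pair of patterns, computes the four partial
#' similarities and the GScore, and retains pairs whose GScore is strictly
#' greater than `threshold`. Retained pairs are sorted by GScore
#' descending, ties broken by the pair of anchor labels, so the output is
#' independent of evaluation order.
#'
#' @param desc_a,desc_b lists of `descriptor_set` from
#'   [describe_patterns()].
#' @param weights a [score_weights()] list.
#' @param threshold GScore retention threshold in percent; a pair is kept
#'   when GScore > threshold.
#' @return object of class `pair_comparison`: list with `scores` (data
#'   frame pattern_a, pattern_b, sdist, snbe, stsp, ssc, gscore),
#'   `n_evaluated`, `n_retained`, `threshold` and `diagnostic` (non-empty
#'   when nothing survived the filter).
#' @export
compare_all <- function(desc_a, desc_b, weights = score_weights(),
                        threshold = 50) {
  if (!inherits(weights, "score_weights")) {
    weights <- do.call(score_weights, as.list(weights))
  }
  empty <- data.frame(pattern_a = character(), pattern_b = character(),
                      sdist = numeric(), snbe = numeric(), stsp = numeric(),
                      ssc = numeric(), gscore = numeric(),
                      stringsAsFactors = FALSE)
  if (length(desc_a) == 0 || length(desc_b) == 0) {
    return(structure(list(scores = empty, n_evaluated = 0L, n_retained = 0L,
                          threshold = threshold,
                          diagnostic = "no patterns to compare on at least one side"),
                     class = "pair_comparison"))
  }
  na <- length(desc_a)
  nb <- length(desc_b)
  rows <- vector("list", na * nb)
  k <- 0L
  for (i in seq_len(na)) {
    da <- desc_a[[i]]
    for (j in seq_len(nb)) {
      db <- desc_b[[j]]
      p_dist <- sdist(da$dist, db$dist)
      p_nbe <- snbe(da$nbe, db$nbe)
      p_tsp <- stsp(da$tsp, db$tsp)
      p_sc <- ssc(da$sc, db$sc)
      g <- gscore(p_dist, p_nbe, p_tsp, p_sc, weights)
      if (g > threshold) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          pattern_a = da$pattern_ref, pattern_b = db$pattern_ref,
          sdist = p_dist, snbe = p_nbe, stsp = p_tsp, ssc = p_sc,
          gscore = g, stringsAsFactors = FALSE
        )
      }
    }
  }
  scores <- if (k > 0) do.call(rbind, rows[seq_len(k)]) else empty
  ord <- order(-scores$gscore, scores$pattern_a, scores$pattern_b)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  structure(
    list(scores = scores, n_evaluated = na * nb, n_retained = nrow(scores),
         threshold = threshold,
         diagnostic = if (nrow(scores) == 0)
           sprintf("no pair exceeded GScore threshold %s among %d evaluated",
                   format(threshold), na * nb) else ""),
    class = "pair_comparison"
  )
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat("pair_comparison:", x$n_evaluated, "pairs evaluated,",
      x$n_retained, "retained (GScore >", x$threshold, ")\n")
  if (x$n_retained > 0) {
    top <- utils::head(x$scores, 5)
    top[, 3:7] <- round(top[, 3:7], 1)
    print(top)
  } else if (nzchar(x$diagnostic)) {
    cat(x$diagnostic, "\n")
  }
  invisible(x)
}
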