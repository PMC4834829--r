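# one grid point anchoring the full residue set, for descriptor tests
whole_set_pattern <- function(spec) {
  m <- fixture_model(spec)
  g <- build_grid(m, gr = 1000)
  pats <- detect_patterns(m, g, detection_params(nt = 0, ft = 1000,
                                                 min_residues = 2))
  list(model = m, pattern = pats[[1]])
}

equilateral_spec <- function(aa3 = "ALA", side = 6) {
  h <- side * sqrt(3) / 2
  data.frame(chain = "A", resno = 1:3, aa3 = aa3,
             x = c(0, side, side / 2), y = c(0, 0, h), z = 0)
}

test_that("pair tokens canonicalize letter order and round half up", {
  expect_equal(pair_token("R", "L", 5.0), "L5R")
  expect_equal(pair_token("L", "R", 5.0), "L5R")
  expect_equal(pair_token("A", "A", 4.49), "A4A")
  expect_equal(pair_token("G", "W", 7.5), "G8W")   # half rounds up
  expect_equal(pair_token("G", "W", 6.5), "G7W")   # also at even targets
  expect_equal(pair_token("A", "C", 0.2), "A0C")
  expect_error(pair_token("X", "A", 1), "unknown")
  expect_error(pair_token("A", "A", -1), "non-negative")
})

test_that("distance descriptor has n(n-1)/2 tokens built from center geometry", {
  eq <- whole_set_pattern(equilateral_spec())
  expect_equal(dist_descriptor(eq$pattern, eq$model), c("A6A", "A6A", "A6A"))
  ws <- whole_set_pattern(random_spec(5, seed = 2))
  expect_length(dist_descriptor(ws$pattern, ws$model), 10)  # 5*4/2
  ws3 <- whole_set_pattern(random_spec(3, seed = 4))
  expect_length(dist_descriptor(ws3$pattern, ws3$model), 3)
})

test_that("NbE descriptor sums tabulated per-residue energies", {
  tab <- c(A = -1.2, D = -3.1)
  two_ala <- whole_set_pattern(data.frame(chain = "A", resno = 1:2,
                                          aa3 = "ALA", x = c(0, 4), y = 0,
                                          z = 0))
  expect_equal(nbe_descriptor(two_ala$pattern, two_ala$model, tab), -2.4)
  expect_error(
    nbe_descriptor(two_ala$pattern, two_ala$model, c(D = -3.1)),
    "missing from energy table: A"
  )
  # identical compositions give equal sums under any table
  sp1 <- five_residue_spec(1:5)
  sp2 <- five_residue_spec(11:15)
  sp2[, c("x", "y", "z")] <- sp2[, c("z", "x", "y")] * 1.1
  w1 <- whole_set_pattern(sp1)
  w2 <- whole_set_pattern(sp2)
  expect_equal(nbe_descriptor(w1$pattern, w1$model),
               nbe_descriptor(w2$pattern, w2$model))
})

test_that("physicochemical categories follow the eight-group scheme", {
  expect_equal(residue_category(c("G", "A", "V", "L", "I")), rep("A", 5))
  expect_equal(residue_category(c("F", "Y", "W")), rep("B", 3))
  expect_equal(residue_category(c("S", "T")), rep("C", 2))
  expect_equal(residue_category(c("D", "E")), rep("D", 2))
  expect_equal(residue_category(c("N", "Q")), rep("E", 2))
  expect_equal(residue_category(c("R", "K", "H")), rep("F", 3))
  expect_equal(residue_category(c("C", "M")), rep("G", 2))
  expect_equal(residue_category("P"), "H")
  expect_error(residue_category("Z"), "unknown")
  # Sc descriptor of the ASP/PRO/SER/GLU/ARG pattern
  w <- whole_set_pattern(five_residue_spec(1:5))
  expect_setequal(sc_descriptor(w$pattern, w$model), c("D", "H", "C", "D", "F"))
  expect_length(sc_descriptor(w$pattern, w$model), 5)
})

test_that("TSP tours are optimal for small n (brute-force oracle)", {
  # unit square: perimeter order, length 4, never the diagonals
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  tour <- solve_tsp(sq)
  expect_equal(attr(tour, "length"), 4)
  # collinear points: out-and-back, length 4
  line <- cbind(c(0, 1, 2), 0, 0)
  expect_equal(attr(solve_tsp(line), "length"), 4)
  expect_error(solve_tsp(line[1:2, ]), "at least 3")
  # random instances against exhaustive enumeration
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:8, 1)
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
    expect_equal(attr(solve_tsp(pts), "length"), brute_tsp_length(pts),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("heuristic tours (n > 10) are valid cycles no worse than greedy", {
  set.seed(8)
  pts <- cbind(runif(14, 0, 20), runif(14, 0, 20), runif(14, 0, 20))
  tour <- solve_tsp(pts)
  expect_setequal(tour, 1:14)
  # 2-opt can only improve on the nearest-neighbour construction it starts
  # from; sanity-check against the average random tour
  set.seed(9)
  rand_len <- mean(replicate(50, {
    p <- c(1, sample(2:14))
    D <- as.matrix(dist(pts))
    sum(D[cbind(p, c(p[-1], p[1]))])
  }))
  expect_lt(attr(tour, "length"), rand_len)
})

test_that("perimeter descriptor emits n tour-edge tokens consistent with Dist", {
  eq <- whole_set_pattern(equilateral_spec())
  expect_equal(tsp_descriptor(eq$pattern, eq$model), c("A6A", "A6A", "A6A"))
  # square of ALA, side 5: optimal tour uses the four sides
  sqspec <- data.frame(chain = "A", resno = 1:4, aa3 = "ALA",
                       x = c(0, 5, 5, 0), y = c(0, 0, 5, 5), z = 0)
  wsq <- whole_set_pattern(sqspec)
  expect_equal(sort(tsp_descriptor(wsq$pattern, wsq$model)), rep("A5A", 4))
  ws <- whole_set_pattern(random_spec(5, seed = 12))
  tsp <- tsp_descriptor(ws$pattern, ws$model)
  expect_length(tsp, 5)
  # every tour edge is a residue pair, so its token also occurs in Dist
  dist_tokens <- dist_descriptor(ws$pattern, ws$model)
  for (tok in unique(tsp)) {
    expect_gte(sum(dist_tokens == tok), sum(tsp == tok))
  }
})

test_that("descriptors are invariant under residue input order", {
  spec <- random_spec(6, seed = 31)
  perm <- c(4, 1, 6, 3, 5, 2)
  spec_perm <- spec[perm, ]       # same residues, permuted file order
  w1 <- whole_set_pattern(spec)
  w2 <- whole_set_pattern(spec_perm)
  expect_equal(sort(dist_descriptor(w1$pattern, w1$model)),
               sort(dist_descriptor(w2$pattern, w2$model)))
  expect_equal(sort(tsp_descriptor(w1$pattern, w1$model)),
               sort(tsp_descriptor(w2$pattern, w2$model)))
  expect_equal(sort(sc_descriptor(w1$pattern, w1$model)),
               sort(sc_descriptor(w2$pattern, w2$model)))
  expect_equal(nbe_descriptor(w1$pattern, w1$model),
               nbe_descriptor(w2$pattern, w2$model))
})

test_that("descriptor sets carry the required cardinalities on random patterns", {
  m <- fixture_model(random_spec(20, box = 18, seed = 44))
  g <- build_grid(m, gr = 10)
  pats <- detect_patterns(m, g, detection_params(nt = 3, ft = 10))
  desc <- describe_patterns(pats, m)
  expect_gt(length(desc), 0)
  for (d in desc) {
    expect_length(d$dist, d$n * (d$n - 1) / 2)
    expect_length(d$sc, d$n)
    expect_length(d$tsp, d$n)
    expect_true(is.finite(d$nbe))
  }
})

test_that("energy tables are read, validated and complete", {
  tab <- default_energy_table()
  expect_length(tab, 20)
  expect_true(all(is.finite(tab)))
  expect_setequal(names(tab), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("# partial table", "A\t-1.0"), bad)
  expect_error(read_energy_table(bad), "lacks residue")
})
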