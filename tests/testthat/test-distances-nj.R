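test_that("ML distances: closed form, saturation cap, missing signal", {
  expect_identical(ml_distance("ACGTACGT", "ACGTACGT"), 0)
  a <- strsplit(paste(rep("A", 10), collapse = ""), "")[[1]]
  b <- c(rep("A", 7), rep("C", 3))          # p = 0.3
  expect_equal(ml_distance(a, b), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_identical(ml_distance(rep("A", 8), rep("C", 8)), 5)   # saturated
  expect_true(is.na(ml_distance(c("A", "?", "-"), c("?", "C", "N"))))
})

test_that("HKY distance matches a grid-search oracle", {
  set.seed(31)
  model <- substitution_model("HKY", freqs = c(.3, .2, .2, .3), kappa = 3)
  tree <- ape::read.tree(text = "(a:0.15,b:0.15);")
  aln <- sim_on_tree(tree, model, 4000)
  d <- ml_distance(aln$mat["a", ], aln$mat["b", ], model)
  counts <- table(factor(aln$mat["a", ], phylodup:::STATE_ORDER),
                  factor(aln$mat["b", ], phylodup:::STATE_ORDER))
  grid <- seq(1e-4, 1, by = 1e-4)
  lls <- vapply(grid, function(t)
    sum(counts * log(model$freqs * transition_matrix(model, t))), 0)
  expect_equal(d, grid[which.max(lls)], tolerance = 1e-3)
})

test_that("NJ reproduces the three-point formulas on 3 taxa", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.4, 0.5, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens["A"]), (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-12)
  expect_equal(unname(lens["B"]), (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(unname(lens["C"]), (0.5 + 0.4 - 0.3) / 2, tolerance = 1e-12)
})

test_that("NJ recovers additive matrices exactly (topology and lengths)", {
  set.seed(32)
  for (i in 1:20) {
    true <- ape::unroot(random_tree(8, 0.05, 1))
    D <- stats::cophenetic(true)
    nj <- neighbor_joining(D[true$tip.label, true$tip.label])
    expect_true(same_topology(nj, true))
    D2 <- stats::cophenetic(nj)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
  }
})

test_that("NJ ties join the lowest-index pair and inputs are validated", {
  D <- matrix(1, 4, 4, dimnames = list(paste0("x", 1:4), paste0("x", 1:4)))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  # equidistant taxa: all Q equal, so (x1, x2) must be joined first
  expect_true(any(vapply(tree_splits(tr), function(s)
    setequal(s$side, c("x3", "x4")) || setequal(s$side, c("x1", "x2")), TRUE)))
  pp <- ape::prop.part(ape::root(tr, "x4"))
  D2 <- D; D2[1, 2] <- 2
  expect_error(neighbor_joining(D2), "symmetric")
  D3 <- D; D3[1, 2] <- D3[2, 1] <- NA
  expect_error(neighbor_joining(D3), "missing")
})

test_that("NJ agrees with ape::nj on noisy matrices", {
  set.seed(33)
  for (i in 1:5) {
    true <- ape::unroot(random_tree(10, 0.05, 0.5))
    D <- stats::cophenetic(true)
    D <- D + matrix(runif(100, 0, 0.01), 10, 10)
    D <- (D + t(D)) / 2; diag(D) <- 0
    expect_true(same_topology(neighbor_joining(D), ape::nj(D)))
  }
})

test_that("distance imputation fills class-disjoint pairs for NJ starts", {
  aln <- alignment(c(a = "ACGTACGT????????", b = "AAGTACGT????????",
                     c = "????????ACGTACGT", d = "????????ACCTACGT",
                     e = "ACGTACGTACGTACGT"))
  D <- distance_matrix(aln)
  expect_true(is.na(D["a", "c"]))
  Di <- distance_matrix(aln, impute = TRUE)
  expect_false(anyNA(Di))
  expect_lte(Di["a", "c"], Di["a", "e"] + Di["e", "c"] + 1e-12)
})
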