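test_that("pruning equals exhaustive enumeration on small instances", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(4:5, 1L)
    tree <- random_tree(n)
    model <- random_model()
    aln <- random_alignment(n, sample(5:20, 1L))
    expect_equal(log_likelihood(aln, tree, model),
                 brute_force_loglik(aln, tree, model), tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant to the traversal root", {
  set.seed(22)
  tree <- random_tree(8)
  aln <- random_alignment(8, 60)
  model <- random_model(gamma = TRUE)
  base <- log_likelihood(aln, tree, model)
  for (node in c(10L, 12L, 14L)) {
    rerooted <- ape::root(ape::unroot(tree), node = node, resolve.root = FALSE)
    expect_equal(log_likelihood(aln, rerooted, model), base,
                 tolerance = 1e-9)
  }
})

test_that("single-site closed forms hold at the branch-length extremes", {
  model <- substitution_model("JC")
  tree <- ape::read.tree(text = "(a:0,b:0,(c:25,d:25):0);")
  aln0 <- alignment(c(a = "A", b = "A", c = "C", d = "G"))
  # a,b joined at distance 0 contribute a single stationary draw ln(1/4);
  # c,d at t -> infinity are independent draws
  expect_equal(log_likelihood(alignment(c(a = "A", b = "A")),
                              ape::read.tree(text = "(a:0,b:0);"), model),
               log(0.25), tolerance = 1e-9)
  expect_equal(log_likelihood(alignment(c(a = "A", b = "C")),
                              ape::read.tree(text = "(a:25,b:25);"), model),
               log(0.0625), tolerance = 1e-6)
})

test_that("transition matrix checks: identity, stationarity, closed form", {
  model <- substitution_model("JC")
  expect_equal(transition_matrix(model, 0), diag(4), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_lt(max(abs(transition_matrix(model, 50) - 0.25)), 1e-6)
  P <- transition_matrix(model, 0.1)
  expect_equal(P[1, 2], (1 / 4) * (1 - exp(-4 * 0.1 / 3)), tolerance = 1e-10)
})

test_that("a leaf without sequence data raises a lookup error", {
  tree <- random_tree(5)
  aln <- random_alignment(4, 20, labels = paste0("t", 1:4))
  expect_error(log_likelihood(aln, tree, substitution_model("JC")), "t5")
})

test_that("partitioned likelihood is additive over regions", {
  set.seed(23)
  scheme <- partition_scheme(data.frame(
    name = c("p1", "p2", "ITS"), klass = c("plastid", "plastid", "nuclear"),
    start = c(1, 41, 101), end = c(40, 100, 160)))
  aln <- random_alignment(6, 160)
  tree <- random_tree(6)
  models <- list(p1 = substitution_model("JC"),
                 p2 = substitution_model("HKY", freqs = c(.3, .2, .2, .3)),
                 ITS = substitution_model("GTR", gamma_shape = 1))
  ld <- lik_data(aln, scheme, models = models)
  total <- partitioned_loglik(tree, ld)
  by_hand <- sum(vapply(names(models), function(nm)
    log_likelihood(alignment(aln$mat[, region_columns(scheme, nm)]),
                   tree, models[[nm]]), 0))
  expect_equal(as.numeric(total), by_hand, tolerance = 1e-8)
})

test_that("pruning agrees with an independent implementation (phangorn)", {
  skip_if_not_installed("phangorn")
  set.seed(24)
  tree <- random_tree(8)
  mat <- matrix(sample(c("A", "C", "G", "T"), 8 * 300, TRUE), 8, 300,
                dimnames = list(tree$tip.label, NULL))
  model <- substitution_model("GTR", freqs = c(.3, .2, .2, .3),
                              rates = c(1.5, 3, .5, .8, 2.5, 1),
                              gamma_shape = 0.7)
  fit <- phangorn::pml(tree, phangorn::phyDat(mat), bf = model$freqs,
                       Q = model$exchangeabilities, k = 4L,
                       shape = model$gamma_shape)
  expect_equal(log_likelihood(alignment(mat), tree, model), fit$logLik,
               tolerance = 1e-6)
})
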