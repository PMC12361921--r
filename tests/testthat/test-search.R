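test_that("branch-length optimization ascends and finds a fixed point", {
  set.seed(41)
  true <- random_tree(6, 0.05, 0.4)
  model <- substitution_model("HKY", freqs = c(.3, .2, .2, .3), kappa = 3)
  aln <- sim_on_tree(true, model, 2000)
  start <- true
  start$edge.length <- rep(0.2, nrow(start$edge))
  ll0 <- log_likelihood(aln, start, model)
  opt <- optimize_branch_lengths(start, aln, model)
  expect_gte(attr(opt, "loglik"), ll0)
  # fixed point: a second pass moves nothing beyond tolerance
  opt2 <- optimize_branch_lengths(opt, aln, model)
  expect_lt(abs(attr(opt2, "loglik") - attr(opt, "loglik")), 1e-4)
})

test_that("optimized branch lengths approach the truth on long alignments", {
  set.seed(42)
  true <- random_tree(6, 0.08, 0.35)
  model <- substitution_model("JC")
  aln <- sim_on_tree(true, model, 10000)
  opt <- optimize_branch_lengths(true, aln, model)
  tr_true <- ape::reorder.phylo(ape::unroot(true), "postorder")
  rel <- abs(opt$edge.length - tr_true$edge.length) / tr_true$edge.length
  expect_lt(stats::median(rel), 0.10)
  expect_lt(max(rel), 0.35)
})

test_that("NNI search is an ascent that recovers the true topology", {
  set.seed(43)
  true <- ape::unroot(random_tree(10, 0.05, 0.3))
  model <- substitution_model("HKY", freqs = c(.3, .2, .2, .3), kappa = 2.5)
  aln <- sim_on_tree(true, model, 3000)
  # start at the truth: returned unchanged
  res0 <- nni_search(true, aln, model)
  expect_true(same_topology(res0, true))
  # start from one NNI away: truth recovered
  pert <- phylodup:::nni_move(ape::reorder.phylo(true, "postorder"),
                              phylodup:::internal_edge_rows(
                                ape::reorder.phylo(true, "postorder"))[3L],
                              1L)$tree
  expect_false(same_topology(pert, true))
  ll_start <- attr(optimize_branch_lengths(pert, aln, model), "loglik")
  res <- nni_search(pert, aln, model)
  expect_true(same_topology(res, true))
  expect_gte(attr(res, "loglik"), ll_start)
})

test_that("aBayes posterior: softmax closed form, equality, and bounds", {
  expect_equal(abayes_posterior(c(-50, -50, -50)), 1 / 3, tolerance = 1e-12)
  expect_equal(abayes_posterior(c(-100, -110, -110)),
               1 / (1 + 2 * exp(-10)), tolerance = 1e-12)
  set.seed(44)
  for (i in 1:20) {
    small <- -runif(3, 1, 5)          # naive exponentiation is safe here
    expect_equal(abayes_posterior(small),
                 max(exp(small)) / sum(exp(small)), tolerance = 1e-12)
    lls <- -runif(3, 50, 5000)        # shift invariance at extreme scales
    expect_equal(abayes_posterior(lls), abayes_posterior(lls + 1234.5),
                 tolerance = 1e-12)
    expect_gte(abayes_posterior(lls), 1 / 3)
    expect_lte(abayes_posterior(lls), 1)
  }
})

test_that("aBayes annotation: signal-free data give 1/3, clean data give 1", {
  flat <- alignment(c(a = strrep("A", 50), b = strrep("A", 50),
                      c = strrep("A", 50), d = strrep("A", 50)))
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  tr <- optimize_branch_lengths(tr, flat, substitution_model("JC"))
  ab <- get_supports(abayes_supports(tr, flat, substitution_model("JC")))
  expect_equal(ab$ab[!is.na(ab$ab)], 1 / 3, tolerance = 1e-4)
  set.seed(45)
  true <- random_tree(6, 0.1, 0.3)
  aln <- sim_on_tree(true, substitution_model("JC"), 4000)
  ab2 <- get_supports(abayes_supports(true, aln, substitution_model("JC")))
  expect_true(all(ab2$ab[!is.na(ab2$ab)] > 0.99))
})

test_that("bootstrap supports: seeded reproducibility and strong-signal 100s", {
  set.seed(46)
  true <- ape::unroot(random_tree(6, 0.1, 0.3))
  aln <- sim_on_tree(true, substitution_model("JC"), 4000)
  scheme <- partition_scheme(data.frame(name = c("p", "ITS"),
                                        klass = c("plastid", "nuclear"),
                                        start = c(1, 2001), end = c(2000, 4000)))
  ref <- neighbor_joining(distance_matrix(aln))
  b1 <- bootstrap_supports(aln, scheme, ref, B = 20L, seed = 7L)
  b2 <- bootstrap_supports(aln, scheme, ref, B = 20L, seed = 7L)
  expect_identical(get_supports(b1), get_supports(b2))
  s <- get_supports(b1)$bs
  expect_true(all(s[!is.na(s)] >= 0 & s[!is.na(s)] <= 100))
  expect_true(all(s[!is.na(s)] == 100))   # unambiguous signal
})

test_that("infer_tree recovers topology, rates, and is order-invariant", {
  set.seed(47)
  cfg <- sim_config(n_taxa = 12L, seed = 470L,
                    regions = data.frame(
                      name = c("p1", "p2", "ITS"),
                      klass = c("plastid", "plastid", "nuclear"),
                      length = c(600L, 600L, 600L), rate = c(1, 1, 3)),
                    n_hybrids = 0L)
  bb <- make_benchmark(cfg)
  models <- bench_models(cfg, bb$scheme)
  tr <- infer_tree(bb$aln, bb$scheme, regions = region_names(bb$scheme),
                   models = models, supports = "none")
  expect_true(same_topology(tr, ape::unroot(bb$truth$species)))
  # the search never stops below the truth's own optimized likelihood
  ld <- lik_data(bb$aln, bb$scheme, regions = region_names(bb$scheme),
                 models = models, rates = attr(tr, "rates"))
  ll_truth <- attr(optimize_branch_lengths(ape::unroot(bb$truth$species),
                                           ld), "loglik")
  expect_gte(attr(tr, "loglik"), ll_truth - 1e-6)
  rates <- attr(tr, "rates")
  expect_gt(rates[["ITS"]] / rates[["p1"]], 1.8)   # 3x vs 1x, within 15%ish
  perm <- sample(bb$aln$taxa)
  tr2 <- infer_tree(subset_alignment(bb$aln, taxa = perm), bb$scheme,
                    regions = region_names(bb$scheme), models = models,
                    supports = "none")
  expect_true(same_topology(tr, tr2))
})
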