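test_that("Yule trees have the right shape and are seeded", {
  expect_error(simulate_species_tree(2), "n >= 4")
  tr <- simulate_species_tree(10, seed = 71L)
  expect_equal(nrow(ape::unroot(tr)$edge), 2 * 10 - 3)
  depths <- ape::node.depth.edgelength(tr)
  expect_lt(diff(range(depths[1:10])), 1e-9)          # ultrametric
  tr2 <- simulate_species_tree(10, seed = 71L)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  scaled <- simulate_species_tree(10, seed = 71L, height = 0.3)
  expect_equal(max(ape::node.depth.edgelength(scaled)), 0.3,
               tolerance = 1e-9)
})

test_that("lineage counts match the pure-birth expectation", {
  set.seed(72)
  lam <- 1; t_probe <- 1.0; n_cap <- 40L; reps <- 400L
  counts <- vapply(seq_len(reps), function(i) {
    tr <- simulate_species_tree(n_cap, lambda = lam)
    # lineages at time t = 2 + internal nodes (other than the root) born
    # before t
    depth <- ape::node.depth.edgelength(tr)
    ints <- depth[(n_cap + 2L):(n_cap + tr$Nnode)]
    2 + sum(ints <= t_probe)
  }, 0)
  expected <- 2 * exp(lam * t_probe)
  se <- stats::sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("planted hybrids perturb only their own gene-tree positions", {
  cfg <- sim_config(seed = 73L)
  sp <- simulate_species_tree(cfg$n_taxa, seed = cfg$seed,
                              height = cfg$height)
  truth <- plant_hybrids(sp, cfg)
  expect_equal(nrow(truth$hybrids), 2L)
  non_hyb <- setdiff(sp$tip.label, truth$hybrids$label)
  expect_true(same_topology(restrict_tree(truth$gene_trees$plastid, non_hyb),
                            restrict_tree(sp, non_hyb)))
  expect_true(same_topology(restrict_tree(truth$gene_trees$nuclear, non_hyb),
                            restrict_tree(sp, non_hyb)))
  # the two class gene trees disagree (donor edges at least 4 apart)
  expect_gt(rf_distance(ape::unroot(truth$gene_trees$plastid),
                        ape::unroot(truth$gene_trees$nuclear)), 0)
  cfg_bad <- sim_config(seed = 73L, donor_min_dist = 100L)
  expect_error(plant_hybrids(sp, cfg_bad), "unsatisfiable")
})

test_that("zero branch lengths copy the root state to every taxon", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  set.seed(74)
  mat <- phylodup:::evolve_states(tr, substitution_model("JC"), 50)
  expect_true(all(apply(mat, 2L, function(col) length(unique(col)) == 1L)))
})

test_that("simulated divergence matches the JC mismatch curve", {
  set.seed(75)
  d <- 0.2; L <- 10000L
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  mat <- phylodup:::evolve_states(tr, substitution_model("JC"), L)
  p_hat <- mean(mat["a", ] != mat["b", ])
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / L))
})

test_that("realized base composition follows the root distribution", {
  set.seed(76)
  freqs <- c(0.4, 0.1, 0.2, 0.3)
  model <- substitution_model("GTR", freqs = freqs)
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.02,(c:0.05,d:0.05):0.02);")
  mat <- phylodup:::evolve_states(tr, model, 5000L, root_freqs = freqs)
  obs <- table(factor(mat, c("A", "C", "G", "T"))) / length(mat)
  for (i in 1:4)
    expect_lt(abs(obs[i] - freqs[i]),
              3 * sqrt(freqs[i] * (1 - freqs[i]) / 5000) + 0.01)
})

test_that("benchmark bundles are byte-identical under a fixed seed", {
  cfg <- sim_config(n_taxa = 8L, n_hybrids = 1L, donor_min_dist = 3L,
                    seed = 77L,
                    regions = data.frame(
                      name = c("p1", "ITS"), klass = c("plastid", "nuclear"),
                      length = c(150L, 150L), rate = c(1, 2)))
  d1 <- file.path(tempdir(), "bench_a"); d2 <- file.path(tempdir(), "bench_b")
  make_benchmark(cfg, d1); make_benchmark(cfg, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  # reload passes validation and matches the in-memory bundle
  bb <- make_benchmark(cfg)
  back <- read_alignment(file.path(d1, "alignment.fasta"))
  expect_identical(back$mat, bb$aln$mat)
  sch <- read_partitions(file.path(d1, "partitions.txt"), back$n_columns)
  expect_identical(class_columns(sch, "nuclear"),
                   class_columns(bb$scheme, "nuclear"))
  # a different seed changes the data but not the shape
  cfg2 <- sim_config(n_taxa = 8L, n_hybrids = 1L, donor_min_dist = 3L,
                     seed = 78L,
                     regions = cfg$regions)
  bb2 <- make_benchmark(cfg2)
  expect_identical(dim(bb2$aln$mat), dim(bb$aln$mat))
  expect_false(identical(bb2$aln$mat, bb$aln$mat))
})
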