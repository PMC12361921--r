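# shared fixture: a 12-taxon benchmark with one planted hybrid
local_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_taxa = 12L, n_hybrids = 1L, donor_min_dist = 4L,
                        seed = 610L,
                        regions = data.frame(
                          name = c("p1", "p2", "ITS"),
                          klass = c("plastid", "plastid", "nuclear"),
                          length = c(600L, 600L, 600L), rate = c(1, 1, 2)))
      bb <- make_benchmark(cfg)
      models <- bench_models(cfg, bb$scheme)
      core <- build_core(bb$aln, bb$scheme, bb$truth$hybrids$label,
                         seed = 611L, models = models, verify = FALSE,
                         supports = "abayes")
      cache <<- list(cfg = cfg, bb = bb, models = models, core = core)
    }
    cache
  }
})

test_that("build_core without flags returns the full combined dataset", {
  fx <- local_bench()
  core_all <- build_core(fx$bb$aln, fx$bb$scheme, NULL, seed = 612L,
                         models = fx$models, verify = FALSE,
                         supports = "none")
  expect_setequal(core_all$tree$tip.label, fx$bb$aln$taxa)
  expect_equal(nrow(core_all$excluded), 0L)
})

test_that("build_core enforces the minimum-size precondition", {
  fx <- local_bench()
  expect_error(build_core(fx$bb$aln, fx$bb$scheme,
                          fx$bb$aln$taxa[1:9], seed = 1L,
                          models = fx$models, verify = FALSE),
               "fewer than 4")
})

test_that("combining incongruent data fails hard, never silently", {
  fx <- local_bench()
  # "flagging" an innocent taxon leaves the hybrid's conflict in place
  innocent <- setdiff(fx$bb$aln$taxa, fx$bb$truth$hybrids$label)[1L]
  expect_error(build_core(fx$bb$aln, fx$bb$scheme, innocent, seed = 613L,
                          models = fx$models, verify = TRUE,
                          supports = "none"),
               "refusing to combine")
})

test_that("core excluding the hybrid matches the true species backbone", {
  fx <- local_bench()
  expect_true(same_topology(fx$core$tree, ape::unroot(fx$bb$truth$backbone)))
  expect_identical(fx$core$excluded$label, fx$bb$truth$hybrids$label)
})

test_that("make_duplicates yields two complementary single-class entries", {
  fx <- local_bench()
  hyb <- fx$bb$truth$hybrids$label
  entries <- make_duplicates(fx$bb$aln, fx$bb$scheme, hyb)
  expect_length(entries, 2L)
  expect_setequal(vapply(entries, `[[`, "", "klass"),
                  c("nuclear", "plastid"))
  its <- entries[[which(vapply(entries, `[[`, "", "klass") == "nuclear")]]
  nuc_cols <- class_columns(fx$bb$scheme, "nuclear")
  expect_true(all(its$seq[-nuc_cols] == "?"))
  expect_identical(its$seq[nuc_cols],
                   unname(fx$bb$aln$mat[hyb, nuc_cols]))
  expect_error(make_duplicates(fx$bb$aln, fx$bb$scheme, "missing_taxon"),
               "absent")
})

test_that("a specimen with one empty class yields a single entry", {
  scheme <- partition_scheme(data.frame(
    name = c("p", "ITS"), klass = c("plastid", "nuclear"),
    start = c(1, 9), end = c(8, 16)))
  aln <- alignment(c(x = "ACGTACGTACGTACGT", y = "????????ACGTACGT",
                     z = "ACGTACGTACGTACGT", w = "ACGTACGTACGTACGT"))
  expect_message(entries <- make_duplicates(aln, scheme, "y"), "no plastid")
  expect_length(entries, 1L)
  expect_identical(entries[[1L]]$klass, "nuclear")
})

test_that("duplication scales to the 26-specimen case (52 entries)", {
  scheme <- partition_scheme(data.frame(
    name = c("p", "ITS"), klass = c("plastid", "nuclear"),
    start = c(1, 11), end = c(10, 20)))
  aln <- random_alignment(30, 20, labels = sprintf("sp%02d", 1:30))
  entries <- make_duplicates(aln, scheme, sprintf("sp%02d", 1:26))
  expect_length(entries, 52L)
})

test_that("placement LWRs normalize and recover a copied core leaf", {
  fx <- local_bench()
  leaf <- fx$core$core_taxa[3L]
  entry <- list(parent = leaf, label = paste0(leaf, "_PL"),
                klass = "plastid",
                seq = { s <- fx$bb$aln$mat[leaf, ]
                        s[class_columns(fx$bb$scheme, "nuclear")] <- "?"
                        unname(s) })
  # the entry duplicates an existing leaf: drop that leaf's own row name
  aln2 <- fx$bb$aln
  p <- place_entry(entry, fx$core, aln2, fx$bb$scheme)
  expect_equal(sum(p$lwr$lwr), 1, tolerance = 1e-8)
  expect_true(all(p$lwr$lwr >= 0))
  expect_identical(p$best_edge, leaf)      # the leaf's pendant edge
  expect_gt(max(p$lwr$lwr), 0.9)
})

test_that("placement matches a brute-force all-edge grid oracle", {
  fx <- local_bench()
  hyb <- fx$bb$truth$hybrids$label
  entries <- make_duplicates(fx$bb$aln, fx$bb$scheme, hyb)
  en <- entries[[which(vapply(entries, `[[`, "", "klass") == "plastid")]]
  p <- place_entry(en, fx$core, fx$bb$aln, fx$bb$scheme)
  # oracle: whole-tree likelihood of each explicit attachment over a grid
  tr <- phylodup:::eng_tree(fx$core$tree)
  regions <- class_regions(fx$bb$scheme, "plastid")
  mat <- rbind(fx$bb$aln$mat[tr$tip.label, , drop = FALSE],
               matrix(en$seq, 1L, fx$bb$aln$n_columns,
                      dimnames = list(en$label, NULL)))
  grid_best <- vapply(seq_len(nrow(tr$edge)), function(e) {
    att <- phylodup:::attach_tip(tr, e, en$label, pendant = 0.05)
    max(vapply(seq(0, 0.5, by = 0.01), function(t) {
      att$edge.length[which(att$edge[, 2L] == length(att$tip.label))] <- t
      sum(vapply(regions, function(nm)
        log_likelihood(alignment(mat[, region_columns(fx$bb$scheme, nm)]),
                       att, fx$models[[nm]]), 0))
    }, 0))
  }, 0)
  expect_identical(p$best_row, which.max(grid_best))
  expect_equal(p$loglik, max(grid_best), tolerance = 1e-2)
})

test_that("individual analysis is invariant to specimen processing order", {
  fx <- local_bench()
  hyb <- fx$bb$truth$hybrids$label
  entries <- make_duplicates(fx$bb$aln, fx$bb$scheme, hyb)
  ind1 <- analyze_individually(entries, fx$core, fx$bb$aln, fx$bb$scheme)
  ind2 <- analyze_individually(rev(entries), fx$core, fx$bb$aln,
                               fx$bb$scheme)
  for (nm in names(ind1$placements))
    expect_identical(ind1$placements[[nm]]$best_edge,
                     ind2$placements[[nm]]$best_edge)
})

test_that("expanded inference with an empty group returns the core tree", {
  fx <- local_bench()
  expect_identical(expanded_inference(fx$core, character(0), fx$bb$aln,
                                      fx$bb$scheme), fx$core$tree)
})
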