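mk_split <- function(side, universe) {
  list(side = sort(side), universe = sort(universe), bs = NA, ab = NA,
       klass = NA)
}

test_that("split incompatibility implements the four-block criterion", {
  u <- as.character(1:6)
  a <- mk_split(c("1", "2", "3"), u)
  b <- mk_split(c("1", "2", "4"), u)
  expect_true(incompatible(a, b))
  expect_true(incompatible(b, a))                      # symmetric
  c2 <- mk_split(c("1", "2"), u)
  d2 <- mk_split(c("1", "2", "3"), u)
  expect_false(incompatible(c2, d2))                   # one empty block
  # trivial restriction is never incompatible
  expect_false(incompatible(a, b, shared = c("1", "2", "4")))
})

test_that("strong splits honor thresholds and and/or semantics", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  tr <- set_supports(tr, bs = c(NA, 97, 94, 96), ab = c(NA, 0.95, 0.94, 0.90))
  s_or <- strong_splits(tr, "or")
  s_and <- strong_splits(tr, "and")
  u <- sort(tr$tip.label)
  separates <- function(splits, grp) any(vapply(splits, function(s)
    setequal(s$side, grp) || setequal(s$side, setdiff(u, grp)), TRUE))
  expect_true(separates(s_or, c("a", "b")))    # 97/0.95
  expect_false(separates(s_or, c("c", "d")))   # 94/0.94
  expect_true(separates(s_or, c("e", "f")))    # 96, or-pass
  expect_false(separates(s_and, c("e", "f")))  # 96/0.90, and-fail
  bare <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_warning(out <- strong_splits(bare), "no support")
  expect_length(out, 0L)
})

test_that("incompatibility agrees with the exhaustive tree-display oracle", {
  skip_if_not_installed("phangorn")
  all7 <- phangorn::allTrees(7, rooted = FALSE, tip.label = paste0("t", 1:7))
  displayed <- new.env()
  for (k in seq_along(all7)) {
    m <- ape_split_masks(all7[[k]])   # [[ restores compressed tip labels
    stopifnot(length(m) == 4L)
    for (i in seq_along(m)) for (j in seq_len(i))
      assign(paste(m[j], m[i]), TRUE, envir = displayed)
  }
  labs <- paste0("t", 1:7)
  mask_of <- function(side) {
    bits <- sum(2^(match(sort(side), sort(labs)) - 1L))
    if (bitwAnd(bits, 1L) == 1L) bits <- bitwAnd(bitwNot(bits), 2^7 - 1L)
    bits
  }
  set.seed(51)
  for (rep in 1:40) {
    t1 <- random_tree(7); t2 <- random_tree(7)
    s1 <- tree_splits(t1); s2 <- tree_splits(t2)
    for (a in s1) for (b in s2) {
      m <- sort(c(mask_of(a$side), mask_of(b$side)))
      can_display <- !is.null(get0(paste(m[1], m[2]), envir = displayed))
      expect_identical(incompatible(a, b), !can_display)
    }
  }
})

test_that("identical annotated trees yield no hard conflicts", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  tr <- set_supports(tr, bs = c(NA, 100, 100, 100), ab = c(NA, 1, 1, 1))
  expect_length(detect_hard_conflicts(tr, tr), 0L)
})

test_that("an NNI swap between strongly supported trees is detected", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1,(e:1,f:1):1);")
  t1 <- set_supports(t1, bs = rep(100, t1$Nnode), ab = rep(1, t1$Nnode))
  t2 <- set_supports(t2, bs = rep(100, t2$Nnode), ab = rep(1, t2$Nnode))
  conf <- detect_hard_conflicts(t1, t2)
  expect_gt(length(conf), 0L)
  # every conflict involves the swapped taxa b/c
  expect_true(all(vapply(conf, function(cf)
    any(c("b", "c") %in% unlist(cf$blocks)), TRUE)))
  t3 <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(detect_hard_conflicts(t1, t3), "fewer than 4")
})

test_that("no conflicts means no re-inference and all-congruent flags", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  tr <- set_supports(tr, bs = c(NA, 100), ab = c(NA, 1))
  conf <- detect_hard_conflicts(tr, tr)
  expect_length(conf, 0L)
})

test_that("a planted hybrid is attributed by leave-one-out testing", {
  cfg <- sim_config(n_taxa = 12L, n_hybrids = 1L, donor_min_dist = 4L,
                    seed = 520L,
                    regions = data.frame(
                      name = c("p1", "p2", "ITS"),
                      klass = c("plastid", "plastid", "nuclear"),
                      length = c(600L, 600L, 600L), rate = c(1, 1, 2)))
  bb <- make_benchmark(cfg)
  models <- bench_models(cfg, bb$scheme)
  tn <- infer_tree(bb$aln, bb$scheme, klass = "nuclear", models = models,
                   supports = "abayes")
  tp <- infer_tree(bb$aln, bb$scheme, klass = "plastid", models = models,
                   supports = "abayes")
  conf <- detect_hard_conflicts(tn, tp)
  expect_gt(length(conf), 0L)
  fl <- attribute_specimens(bb$aln, bb$scheme, conf, tn, tp, seed = 521L)
  expect_true(fl$converged)
  expect_identical(fl$removed, bb$truth$hybrids$label)
  expect_identical(
    fl$flags$verdict[fl$flags$label == bb$truth$hybrids$label], "incongruent")
  # verdict is incongruent iff conflicts were resolved by the removal
  expect_true(all((fl$flags$verdict == "incongruent") ==
                  nzchar(fl$flags$conflicts_resolved)))
})
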