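# hand-built core tree: two well-separated four-taxon clades plus two
# outlying taxa, all edges strongly supported
mk_core <- function() {
  txt <- "(((a1:1,a2:1):1,(a3:1,a4:1):1):1,((b1:1,b2:1):1,(b3:1,b4:1):1):1,(x1:1,x2:1):1);"
  tr <- ape::read.tree(text = txt)
  set_supports(tr, bs = rep(100, tr$Nnode), ab = rep(1, tr$Nnode))
}

fake_placement <- function(parent, klass, side_tips, core_tree) {
  edges <- phylodup:::core_edge_table(core_tree)
  row <- which(edges$key == paste(sort(side_tips), collapse = "|"))[1L]
  stopifnot(!is.na(row))
  structure(list(label = paste0(parent, if (klass == "nuclear") "_ITS" else "_PL"),
                 parent = parent, klass = klass, best_edge = edges$key[row],
                 best_row = row, pendant_length = 0.01, loglik = -1,
                 lwr = data.frame(edge = edges$key, row = edges$row,
                                  loglik = -1, pendant = 0,
                                  lwr = 1 / nrow(edges))),
            class = "dup_placement")
}

test_that("user clade maps are validated against the core tree", {
  core <- mk_core()
  cm <- clade_map(core, clades = list(A = paste0("a", 1:4),
                                      B = paste0("b", 1:4)))
  expect_named(cm, c("A", "B"))
  expect_error(clade_map(core, clades = list(bad = c("a1", "b1"))),
               "not a clade")
  expect_error(clade_map(core, clades = list(c("a1", "a2"))), "names")
})

test_that("auto clade map contains the strongly supported groups", {
  core <- mk_core()
  cm <- clade_map(core)
  sides <- unname(lapply(cm, sort))
  expect_true(any(vapply(sides, setequal, TRUE, paste0("a", 1:4))))
  expect_true(any(vapply(sides, setequal, TRUE, c("b3", "b4"))))
})

test_that("placements are assigned to the smallest containing clade", {
  core <- mk_core()
  cm <- clade_map(core, clades = list(A = paste0("a", 1:4),
                                      B = paste0("b", 1:4)))
  p_in <- fake_placement("s1", "plastid", c("a1", "a2"), core)
  expect_identical(assign_clade(p_in, cm, core), "A")
  p_stem <- fake_placement("s1", "plastid", paste0("b", 1:4), core)
  expect_identical(assign_clade(p_stem, cm, core), "B")
  p_out <- fake_placement("s1", "plastid", "x1", core)
  expect_match(assign_clade(p_out, cm, core), "between\\(A,B\\)")
})

test_that("pattern classification partitions specimens by clade pair", {
  core <- mk_core()
  cm <- clade_map(core, clades = list(A = paste0("a", 1:4),
                                      B = paste0("b", 1:4)))
  pls <- list(
    fake_placement("s1", "plastid", c("a1", "a2"), core),
    fake_placement("s1", "nuclear", c("b1", "b2"), core),
    fake_placement("s2", "plastid", c("a3", "a4"), core),
    fake_placement("s2", "nuclear", c("b3", "b4"), core),
    fake_placement("s3", "plastid", c("b1", "b2"), core),
    fake_placement("s3", "nuclear", c("b1", "b2"), core))
  names(pls) <- vapply(pls, `[[`, "", "label")
  cl <- classify_patterns(pls, cm, core)
  expect_setequal(unlist(cl$groups), c("s1", "s2", "s3"))
  expect_equal(sum(lengths(cl$groups)), 3L)          # disjoint, exhaustive
  expect_true(setequal(cl$groups[[1L]], c("s1", "s2")))  # same (A, B) pattern
  expect_false(cl$patterns$discordant[cl$patterns$specimen == "s3"])
})

test_that("floating groups require >= 2 ITS-only members with divergent plastids", {
  core <- mk_core()
  cm <- clade_map(core, clades = list(A = paste0("a", 1:4),
                                      B = paste0("b", 1:4)))
  # expanded tree: s1_ITS and s2_ITS form their own supported clade
  ex <- ape::read.tree(text = paste0(
    "(((a1:1,a2:1):1,(a3:1,a4:1):1):1,((b1:1,b2:1):1,(b3:1,b4:1):1):1,",
    "((s1_ITS:1,s2_ITS:1):1,(x1:1,x2:1):1):1);"))
  ex <- set_supports(ex, bs = rep(100, ex$Nnode), ab = rep(1, ex$Nnode))
  mk_pls <- function(p1_side, p2_side) {
    pls <- list(fake_placement("s1", "plastid", p1_side, core),
                fake_placement("s2", "plastid", p2_side, core))
    names(pls) <- vapply(pls, `[[`, "", "label")
    pls
  }
  fg <- find_floating_groups(ex, mk_pls(c("a1", "a2"), c("b1", "b2")),
                             cm, core)
  expect_length(fg, 1L)
  expect_setequal(fg[[1L]]$members, c("s1_ITS", "s2_ITS"))
  expect_length(fg[[1L]]$plastid_clades, 2L)
  # shared plastid destination: condition fails
  expect_length(find_floating_groups(ex, mk_pls(c("a1", "a2"), c("a3", "a4")),
                                     cm, core), 0L)
  # no duplicated entries at all
  ex2 <- mk_core()
  expect_length(find_floating_groups(ex2, list(), cm, core), 0L)
})
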