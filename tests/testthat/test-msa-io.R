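test_that("alignment construction validates lengths, labels and characters", {
  aln <- alignment(c(a = "ACGTACGTAC", b = "ACGT-CGTAC", c = "ACG?ACGUAC"))
  expect_equal(aln$n_columns, 10L)
  expect_equal(length(aln$taxa), 3L)
  expect_equal(unname(aln$mat["c", 8L]), "T")    # U folded into T
  expect_error(alignment(c(a = "ACGTACGTAC", b = "ACGTACGTA")), "record 2")
  expect_error(alignment(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(alignment(c(a = "ACXT", b = "ACGT")), "invalid characters")
})

test_that("FASTA read/write round-trips, preserving gaps and missing", {
  aln <- alignment(c(sp1 = "ACGT-CGT??", sp2 = "acgtacgtnn", sp3 = "ACGWACGTAC"))
  path <- tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path)
  expect_identical(back$mat, aln$mat)
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTAC", ">b", "ACGTA"), bad)
  expect_error(read_alignment(bad), "unequal")
})

test_that("partition files convert 1-based inclusive spans and catch overlap", {
  path <- tempfile()
  writeLines(c("# five regions shaped like a plastid+ITS matrix",
               "rps16-trnK, plastid, 1-975",
               "rps16-intron, plastid, 976-1939",
               "rpl32-trnL, plastid, 1940-2876",
               "ndhA-intron, plastid, 2877-4112",
               "ITS, nuclear, 4113-4910"), path)
  scheme <- read_partitions(path, n_columns = 4910L)
  expect_equal(length(class_regions(scheme, "plastid")), 4L)
  expect_equal(length(class_regions(scheme, "nuclear")), 1L)
  expect_equal(length(class_columns(scheme, "plastid")), 4112L)
  expect_equal(length(region_columns(scheme, "ITS")), 798L)
  expect_equal(range(region_columns(scheme, "ITS")), c(4113L, 4910L))
  expect_error(partition_scheme(data.frame(
    name = c("a", "b"), klass = "plastid", start = c(1, 50), end = c(60, 90))),
    "overlap")
  expect_error(read_partitions(path, n_columns = 4000L), "4910")
})

test_that("subsetting by class and taxa partitions the columns", {
  scheme <- partition_scheme(data.frame(
    name = c("p1", "p2", "ITS"), klass = c("plastid", "plastid", "nuclear"),
    start = c(1, 11, 31), end = c(10, 30, 50)))
  aln <- random_alignment(6, 50)
  pl <- subset_alignment(aln, scheme, "plastid")
  nu <- subset_alignment(aln, scheme, "nuclear")
  expect_equal(pl$n_columns + nu$n_columns, aln$n_columns)
  expect_identical(cbind(pl$mat, nu$mat), aln$mat)
  expect_identical(subset_alignment(aln)$mat, aln$mat)
  expect_error(subset_alignment(aln, scheme, "plastid", taxa = "nope"),
               "not in alignment")
})

test_that("newick trees round-trip with branch lengths and dual supports", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.123456789):0.07);")
  tr <- set_supports(tr, bs = c(NA, 97, NA), ab = c(NA, 0.95, 0.9))
  path <- tempfile(fileext = ".nwk")
  write_tree_file(tr, path)
  back <- read_tree_file(path)
  expect_true(same_topology(tr, back))
  expect_lt(max(abs(sort(back$edge.length) - sort(tr$edge.length))), 1e-9)
  sup <- get_supports(back)
  expect_true(any(sup$bs == 97 & sup$ab == 0.95, na.rm = TRUE))
  expect_true(any(is.na(sup$bs) & sup$ab == 0.9))
})

test_that("bracketed-comment support encoding is accepted on read", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((a:0.1,b:0.2)[&bs=88,ab=0.99]:0.05,c:0.3,d:0.1);", path)
  tr <- read_tree_file(path)
  sup <- get_supports(tr)
  expect_true(any(sup$bs == 88 & sup$ab == 0.99, na.rm = TRUE))
})

test_that("malformed newick fails with a character offset", {
  p1 <- tempfile(); writeLines("((a,b),(c,d);", p1)
  expect_error(read_tree_file(p1), "unclosed")
  p2 <- tempfile(); writeLines("((a,b)),c);", p2)
  expect_error(read_tree_file(p2), "character 10")
  p3 <- tempfile(); writeLines("((a,b),c)", p3)
  expect_error(read_tree_file(p3), "terminator")
})

test_that("random trees round-trip through newick (property)", {
  set.seed(41)
  for (i in 1:8) {
    tr <- ape::unroot(random_tree(20))
    tr <- set_supports(tr, bs = sample(c(NA, 50:100), tr$Nnode, TRUE),
                       ab = round(runif(tr$Nnode, 1/3, 1), 4))
    path <- tempfile(fileext = ".nwk")
    write_tree_file(tr, path)
    back <- read_tree_file(path)
    expect_true(same_topology(tr, back))
  }
})
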