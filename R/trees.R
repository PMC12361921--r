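# Trees are ape "phylo" objects, handled unrooted.  Dual branch supports
# (bootstrap percentage and aBayes posterior) live in node labels of the
# form "bs/ab" (e.g. "97/0.951"); either value may be NA.  This is the
# canonical write form; the bracketed comment form "[&bs=97,ab=0.951]" is
# also accepted on read.

#' Attach bootstrap / aBayes supports to internal nodes
#'
#' @param tree a \code{phylo}.
#' @param bs numeric vector of bootstrap percentages, one per internal node
#'   (in node-number order \code{ntip+1 ...}), NA allowed.
#' @param ab numeric vector of aBayes posteriors, same layout.
#' @return the tree with formatted node labels.
#' @export
set_supports <- function(tree, bs = NULL, ab = NULL) {
  n <- tree$Nnode
  if (is.null(bs)) bs <- rep(NA_real_, n)
  if (is.null(ab)) ab <- rep(NA_real_, n)
  stopifnot(length(bs) == n, length(ab) == n)
  fmt <- function(b, a) {
    if (is.na(b) && is.na(a)) return("")
    num <- function(x) format(round(x, 6), trim = TRUE, scientific = FALSE)
    paste0(if (is.na(b)) "NA" else num(b), "/",
           if (is.na(a)) "NA" else num(a))
  }
  tree$node.label <- mapply(fmt, bs, ab)
  tree
}

#' Extract supports from node labels
#'
#' @param tree a \code{phylo} with "bs/ab" node labels (may be absent).
#' @return data frame with columns \code{node}, \code{bs}, \code{ab}, one
#'   row per internal node.
#' @export
get_supports <- function(tree) {
  n <- tree$Nnode
  ntip <- length(tree$tip.label)
  out <- data.frame(node = ntip + seq_len(n), bs = NA_real_, ab = NA_real_)
  lab <- tree$node.label
  if (is.null(lab)) return(out)
  for (i in seq_len(n)) {
    if (is.na(lab[i]) || !nzchar(lab[i])) next
    parts <- strsplit(lab[i], "/", fixed = TRUE)[[1L]]
    if (parts[1L] != "NA")
      out$bs[i] <- suppressWarnings(as.numeric(parts[1L]))
    if (length(parts) > 1L && parts[2L] != "NA")
      out$ab[i] <- suppressWarnings(as.numeric(parts[2L]))
  }
  out
}

#' Write a tree in Newick with dual supports
#' @param tree a \code{phylo} (supports in node labels, see
#'   \code{\link{set_supports}}).
#' @param path output path.
#' @export
write_tree_file <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree, accepting either support encoding
#'
#' Accepts node labels of the form \code{bs/ab} or bracketed metadata
#' comments \code{[&bs=97,ab=0.951]} after internal nodes.
#'
#' @param path path to a Newick file.
#' @return a \code{phylo}.
#' @export
read_tree_file <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed newick: unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed newick: %d unclosed '(' at end of input", depth))
  if (!grepl(";", txt, fixed = TRUE))
    stop(sprintf("malformed newick: missing ';' terminator at character %d",
                 nchar(txt)))
  # comment-style supports -> label-style
  txt <- gsub("\\[&bs=([^,]*),ab=([^]]*)\\]", "\\1/\\2", txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("malformed newick: parser returned no tree")
  tree
}

#' Non-trivial bipartitions (splits) of an unrooted tree
#'
#' Each internal edge of the unrooted tree induces a split of the leaf set.
#' The canonical stored side is the one \emph{not} containing the
#' alphabetically first taxon.  Only non-trivial splits (both sides of size
#' >= 2) are returned.
#'
#' @param tree a \code{phylo}.
#' @param klass optional class tag recorded on each split.
#' @return list of records with fields \code{side} (sorted labels),
#'   \code{universe}, \code{bs}, \code{ab}, \code{klass}, \code{node}.
#' @export
tree_splits <- function(tree, klass = NA_character_) {
  ntip <- length(tree$tip.label)
  universe <- sort(tree$tip.label)
  ref <- universe[1L]
  sup <- get_supports(tree)
  out <- list()
  if (tree$Nnode < 2L && ntip > 3L) return(out)
  for (i in seq_len(tree$Nnode)) {
    node <- ntip + i
    tips <- tip_set(tree, node)
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    side <- if (ref %in% tips) sort(setdiff(universe, tips)) else sort(tips)
    out[[length(out) + 1L]] <- list(side = side, universe = universe,
                                    bs = sup$bs[i], ab = sup$ab[i],
                                    klass = klass, node = node)
  }
  out
}

# tips below an internal node in the ape edge matrix (rooted representation)
tip_set <- function(tree, node) {
  ntip <- length(tree$tip.label)
  desc <- node
  tips <- integer(0)
  while (length(desc)) {
    kids <- tree$edge[tree$edge[, 1L] %in% desc, 2L]
    tips <- c(tips, kids[kids <= ntip])
    desc <- kids[kids > ntip]
  }
  tree$tip.label[tips]
}

# canonical key of a split side within a universe
split_key <- function(side, universe) {
  ref <- sort(universe)[1L]
  side <- sort(side)
  if (ref %in% side) side <- sort(setdiff(universe, side))
  paste(side, collapse = "|")
}

#' Split-set equality of two unrooted trees
#'
#' @param t1,t2 \code{phylo} objects over the same leaf set.
#' @return TRUE if the trees display the same non-trivial splits.
#' @export
same_topology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  u <- sort(t1$tip.label)
  k1 <- sort(vapply(tree_splits(t1), function(s) split_key(s$side, u), ""))
  k2 <- sort(vapply(tree_splits(t2), function(s) split_key(s$side, u), ""))
  identical(k1, k2)
}

#' Robinson-Foulds distance via split sets
#' @param t1,t2 \code{phylo} objects over the same leaf set.
#' @return number of splits present in exactly one tree.
#' @export
rf_distance <- function(t1, t2) {
  u <- sort(t1$tip.label)
  k1 <- vapply(tree_splits(t1), function(s) split_key(s$side, u), "")
  k2 <- vapply(tree_splits(t2), function(s) split_key(s$side, u), "")
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Restrict a tree to a taxon subset (keeping branch lengths)
#' @param tree a \code{phylo}.
#' @param taxa labels to keep.
#' @export
restrict_tree <- function(tree, taxa) {
  drop <- setdiff(tree$tip.label, taxa)
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop)
}
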