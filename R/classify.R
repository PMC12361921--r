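# Phase 3: classify each incongruent specimen's (plastid placement, ITS
# placement) pattern against named core clades, and detect floating ITS
# groups in expanded trees.

#' Named clade map over the core tree
#'
#' Clades are defined relative to the alphabetically first core taxon
#' (treated as reference outgroup for display): each clade is the side of
#' a core split not containing it.  If no map is supplied, strongly
#' supported core clades of at most half the taxa are auto-generated
#' (nested clades allowed; assignment uses the smallest containing clade)
#' and named K1, K2, ... by decreasing size.
#'
#' @param core a \code{dup_core} or core \code{phylo}.
#' @param clades optional named list of leaf sets; each must be a clade
#'   (split side or single leaf) of the core tree.
#' @param mode,bs_min,ab_min strong-support rule for auto-generation.
#' @return named list of leaf sets, class \code{"dup_clademap"}.
#' @export
clade_map <- function(core, clades = NULL, mode = "or", bs_min = 95,
                      ab_min = 0.95) {
  tree <- if (inherits(core, "dup_core")) core$tree else core
  universe <- sort(tree$tip.label)
  sides <- lapply(tree_splits(tree), `[[`, "side")
  if (!is.null(clades)) {
    if (is.null(names(clades)) || any(!nzchar(names(clades))) ||
        anyDuplicated(names(clades)))
      stop("clades must have unique non-empty names")
    for (nm in names(clades)) {
      cl <- sort(clades[[nm]])
      ok <- length(cl) == 1L && cl %in% universe ||
        any(vapply(sides, function(s) setequal(s, cl) ||
                     setequal(setdiff(universe, s), cl), TRUE))
      if (!ok) stop(sprintf("'%s' is not a clade of the core tree", nm))
      clades[[nm]] <- cl
    }
    return(structure(clades, class = "dup_clademap"))
  }
  sides1 <- lapply(strong_splits(tree, mode, bs_min, ab_min), `[[`, "side")
  strong <- c(sides1, lapply(sides1, function(s) setdiff(universe, s)))
  strong <- strong[!duplicated(vapply(strong, paste, "", collapse = "|"))]
  # keep clades at sub-backbone scale (at most half the taxa): placements
  # are then labelled by the smallest containing named clade, which keeps
  # the pattern labels at the granularity of taxonomic sections rather
  # than of near-root backbone splits
  strong <- strong[lengths(strong) <= ceiling(length(universe) / 2)]
  strong <- strong[order(-lengths(strong),
                         vapply(strong, function(s) s[1L], ""))]
  out <- stats::setNames(strong, paste0("K", seq_along(strong)))
  structure(out, class = "dup_clademap")
}

#' Assign a placement to a named clade
#'
#' If the best attachment edge lies inside a named clade's subtree
#' (including its stem edge), that clade's name is returned; otherwise the
#' placement is \code{"between(X,Y)"} where X and Y are the two nearest
#' named clades along the tree (edge-graph distance, ties broken
#' alphabetically).
#'
#' @param placement a \code{dup_placement}.
#' @param clades a \code{dup_clademap} (or NULL: auto-generated).
#' @param core a \code{dup_core} or core \code{phylo}.
#' @return character clade label.
#' @export
assign_clade <- function(placement, clades = NULL, core) {
  tree <- if (inherits(core, "dup_core")) core$tree else core
  if (is.null(clades) || !length(clades)) clades <- clade_map(core)
  tr <- eng_tree(tree)
  clade_of_edge <- edge_clades(tr)
  side <- clade_of_edge[[placement$best_row]]
  inside <- names(clades)[vapply(clades, function(cl)
    length(setdiff(side, cl)) == 0L, TRUE)]
  if (length(inside)) {
    sizes <- lengths(clades[inside])
    return(inside[order(sizes, inside)][1L])   # smallest containing clade
  }
  # nearest named clades on the edge graph (stem edge of each clade)
  D <- edge_graph_dist(tr)
  stems <- vapply(names(clades), function(nm) {
    hit <- which(vapply(clade_of_edge, function(s)
      setequal(s, clades[[nm]]), TRUE))
    if (length(hit)) hit[1L] else NA_integer_
  }, 0L)
  stems <- stems[!is.na(stems)]
  if (length(stems) < 2L) return("unplaced")
  d <- D[placement$best_row, stems]
  ord <- order(d, names(stems))
  pair <- sort(names(stems)[ord[1:2]])
  sprintf("between(%s,%s)", pair[1L], pair[2L])
}

#' Classify discordance patterns of placed specimens
#'
#' The pattern of a specimen is the pair (plastid clade, ITS clade) of its
#' two duplicated entries; specimens are grouped by pattern equality
#' (groups ordered by size, then pattern label).  A specimen whose two
#' entries land in the same clade is non-discordant at clade scale.
#'
#' @param placements list of \code{dup_placement} (both entries per
#'   specimen).
#' @param clades a \code{dup_clademap} or NULL (auto).
#' @param core a \code{dup_core} or core \code{phylo}.
#' @return list: \code{patterns} data frame (specimen, plastid_clade,
#'   its_clade, pattern, discordant), \code{groups} (named list of
#'   specimen sets), \code{clades} (the map used).
#' @export
classify_patterns <- function(placements, clades = NULL, core) {
  if (is.null(clades) || !length(clades)) clades <- clade_map(core)
  parents <- unique(vapply(placements, `[[`, "", "parent"))
  rows <- lapply(parents, function(p) {
    pl <- Filter(function(x) x$parent == p && x$klass == "plastid", placements)
    nu <- Filter(function(x) x$parent == p && x$klass == "nuclear", placements)
    pc <- if (length(pl)) assign_clade(pl[[1L]], clades, core) else NA_character_
    nc <- if (length(nu)) assign_clade(nu[[1L]], clades, core) else NA_character_
    data.frame(specimen = p, plastid_clade = pc, its_clade = nc,
               pattern = paste0("PL:", pc, " ~ ITS:", nc),
               discordant = !identical(pc, nc))
  })
  tab <- do.call(rbind, rows)
  groups <- split(tab$specimen, tab$pattern)
  groups <- groups[order(-lengths(groups), names(groups))]
  list(patterns = tab, groups = groups, clades = clades)
}

#' Detect floating ITS groups in an expanded tree
#'
#' A floating ITS group is a maximal, strongly supported clade of the
#' expanded tree that consists only of duplicated ITS entries (at least
#' two, no core taxa) whose specimens' plastid entries attach to at least
#' two distinct named clades — a homogenized nuclear signal shared by taxa
#' with divergent plastid lineages.
#'
#' @param expanded support-annotated expanded tree (core taxa +
#'   duplicated entries).
#' @param placements list of \code{dup_placement} covering the group
#'   members' plastid entries.
#' @param clades a \code{dup_clademap} or NULL (auto from core).
#' @param core a \code{dup_core} or core \code{phylo}.
#' @param mode,bs_min,ab_min strong-support rule.
#' @return list of floating groups: \code{members} (ITS entry labels),
#'   \code{support} (bs, ab), \code{plastid_clades}.
#' @export
find_floating_groups <- function(expanded, placements, clades = NULL, core,
                                 mode = "or", bs_min = 95, ab_min = 0.95) {
  if (is.null(clades) || !length(clades)) clades <- clade_map(core)
  splits <- strong_splits(expanded, mode, bs_min, ab_min)
  universe <- sort(expanded$tip.label)
  is_its <- function(x) grepl("_ITS$", x)
  is_entry <- function(x) grepl("_(ITS|PL)$", x)
  cand <- list()
  for (s in splits) {
    for (side in list(s$side, setdiff(universe, s$side))) {
      if (length(side) < 2L || !all(is_its(side))) next
      parents <- sub("_ITS$", "", side)
      pl <- Filter(function(x) x$parent %in% parents && x$klass == "plastid",
                   placements)
      dest <- unique(vapply(pl, assign_clade, "", clades = clades, core = core))
      if (length(dest) < 2L) next
      cand[[length(cand) + 1L]] <- list(members = sort(side),
                                        support = c(bs = s$bs, ab = s$ab),
                                        plastid_clades = sort(dest))
    }
  }
  if (!length(cand)) return(list())
  # maximality: drop groups contained in a larger qualifying group
  keep <- vapply(seq_along(cand), function(i)
    !any(vapply(seq_along(cand), function(j)
      j != i && length(setdiff(cand[[i]]$members, cand[[j]]$members)) == 0L &&
        length(cand[[j]]$members) > length(cand[[i]]$members), TRUE)), TRUE)
  cand <- cand[keep]
  # de-duplicate identical member sets (a clade can appear from both sides)
  keys <- vapply(cand, function(g) paste(g$members, collapse = "|"), "")
  cand[!duplicated(keys)]
}
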