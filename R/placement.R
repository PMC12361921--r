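# Phase 2: taxon duplication.  Each flagged specimen re-enters the
# analysis as two single-class entries (label_ITS carrying only nuclear
# characters, label_PL only plastid ones); each entry is located against
# the fixed core tree by likelihood placement with per-edge likelihood
# weight ratios, and groups of specimens with the same discordance pattern
# are re-analyzed by full expanded inference.

#' Create duplicated single-class entries for flagged specimens
#'
#' @param aln,scheme data and partitions.
#' @param flags a \code{dup_flags}, or a character vector of specimen
#'   labels.
#' @return list of entries: \code{parent}, \code{label}
#'   (\code{parent_ITS} / \code{parent_PL}), \code{klass}, \code{seq}
#'   (full-width characters with the complementary class set to \code{?}).
#'   Specimens lacking all data in one class yield only the populated
#'   entry (with a message).
#' @export
make_duplicates <- function(aln, scheme, flags) {
  labels <- if (inherits(flags, "dup_flags")) flags$removed else flags
  missing <- setdiff(labels, aln$taxa)
  if (length(missing))
    stop("flagged specimen absent from alignment: ",
         paste(missing, collapse = ", "))
  nuc_cols <- class_columns(scheme, "nuclear")
  pla_cols <- class_columns(scheme, "plastid")
  out <- list()
  for (lab in labels) {
    row <- aln$mat[lab, ]
    for (kl in c("nuclear", "plastid")) {
      keep_cols <- if (kl == "nuclear") nuc_cols else pla_cols
      seqv <- rep("?", aln$n_columns)
      seqv[keep_cols] <- row[keep_cols]
      if (!any(seqv %in% STATE_ORDER)) {
        message(sprintf("specimen %s has no %s data; entry skipped", lab, kl))
        next
      }
      out[[length(out) + 1L]] <- list(
        parent = lab,
        label = paste0(lab, if (kl == "nuclear") "_ITS" else "_PL"),
        klass = kl, seq = seqv)
    }
  }
  out
}

# postorder core-tree edge table with stable identifiers (child-side tip
# set keys) used to report placements
core_edge_table <- function(core_tree) {
  tr <- eng_tree(core_tree)
  clades <- edge_clades(tr)
  data.frame(row = seq_len(nrow(tr$edge)),
             child = tr$edge[, 2L],
             key = vapply(clades, paste, "", collapse = "|"))
}

#' Place a duplicated entry on the fixed core tree
#'
#' The entry is attached at the midpoint of every core-tree edge in turn
#' with a free pendant branch; only the pendant length is optimized
#' (bracketed 1-D search) while the core topology and branch lengths stay
#' fixed.  The likelihood is computed on the entry's class regions only.
#' Per-edge likelihood weight ratios are the softmax of the attachment
#' log-likelihoods.
#'
#' @param entry an entry from \code{\link{make_duplicates}}.
#' @param core a \code{dup_core} (or a \code{phylo} core tree plus
#'   \code{models}).
#' @param aln,scheme data and partitions.
#' @param models per-region models (default: the core result's).
#' @return list of class \code{"dup_placement"}: \code{label},
#'   \code{klass}, \code{best_edge} (edge key), \code{best_row},
#'   \code{pendant_length}, \code{loglik}, and the full \code{lwr} table.
#' @export
place_entry <- function(entry, core, aln, scheme,
                        models = core$models) {
  core_tree <- if (inherits(core, "dup_core")) core$tree else core
  tr <- eng_tree(core_tree)
  regions <- class_regions(scheme, entry$klass)
  rates <- if (inherits(core, "dup_core") && !is.null(core$rates))
    core$rates[regions] else NULL
  # class alignment over core taxa + the entry
  mat <- rbind(aln$mat[tr$tip.label, , drop = FALSE],
               matrix(entry$seq, 1L, aln$n_columns,
                      dimnames = list(entry$label, NULL)))
  ld <- lik_data(alignment(mat), scheme = scheme, regions = regions,
                 models = models[regions], rates = rates)
  ws <- lik_workspace(ld, c(tr$tip.label, entry$label))
  edges <- core_edge_table(tr)
  informative <- any(entry$seq %in% STATE_ORDER)
  lls <- numeric(nrow(edges)); pend <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    att <- attach_tip(tr, e, entry$label, pendant = 0.05)
    prow <- which(att$edge[, 2L] == length(att$tip.label))
    envs <- ws_envs(ws, att, prow)
    opt <- optimize_edge(env_dobjective(ws, envs, 1L), 0.05, upper = BL_MAX)
    pend[e] <- opt$t; lls[e] <- opt$ll
  }
  if (!informative) {
    warning("entry ", entry$label, " has no informative columns; uniform LWR")
    lwr <- rep(1 / nrow(edges), nrow(edges))
  } else {
    m <- max(lls)
    lwr <- exp(lls - m); lwr <- lwr / sum(lwr)
  }
  best <- which.max(lwr)
  structure(list(label = entry$label, parent = entry$parent,
                 klass = entry$klass, best_edge = edges$key[best],
                 best_row = best, pendant_length = pend[best],
                 loglik = lls[best],
                 lwr = data.frame(edge = edges$key, row = edges$row,
                                  loglik = lls, pendant = pend, lwr = lwr)),
            class = "dup_placement")
}

#' @export
print.dup_placement <- function(x, ...) {
  cat(sprintf("%s (%s): best edge {%s}, LWR %.3f, pendant %.4g\n",
              x$label, x$klass, x$best_edge,
              max(x$lwr$lwr), x$pendant_length))
  invisible(x)
}

#' Place each flagged specimen's entries individually and group by pattern
#'
#' Each specimen's ITS and plastid entries are placed with no other
#' flagged specimen present (the core tree contains none of them), so
#' confounding nuclear copies cannot attract each other.  Specimens are
#' then grouped by their discordance pattern (pair of assigned clades;
#' see \code{\link{classify_patterns}}) into expanded datasets.
#'
#' @param entries from \code{\link{make_duplicates}}.
#' @param core a \code{dup_core}.
#' @param aln,scheme data and partitions.
#' @param clades optional named clade map (default: auto-generated from
#'   strongly supported core clades).
#' @param seed integer seed (unused by the deterministic placement; kept
#'   for interface symmetry).
#' @return list: \code{placements} (list of \code{dup_placement}),
#'   \code{patterns} (data frame), \code{groups} (list of specimen sets).
#' @export
analyze_individually <- function(entries, core, aln, scheme, clades = NULL,
                                 seed = NULL) {
  placements <- lapply(entries, place_entry, core = core, aln = aln,
                       scheme = scheme)
  names(placements) <- vapply(entries, `[[`, "", "label")
  cl <- classify_patterns(placements, clades, core)
  list(placements = placements, patterns = cl$patterns, groups = cl$groups,
       clades = cl$clades)
}

#' Expanded inference: core taxa plus one group's duplicated entries
#'
#' Full re-inference (NJ + NNI + supports) on the core taxa together with
#' both duplicated entries of every specimen in the group — the faithful
#' re-analysis mode behind the expanded datasets, used to display the
#' joint placements and detect floating ITS groups.
#'
#' @param core a \code{dup_core}.
#' @param group character vector of flagged specimen labels.
#' @param aln,scheme data and partitions.
#' @param seed integer seed.
#' @param supports,B support annotation.
#' @param placements optional individual placements; when given, the
#'   search starts from the core tree with every entry grafted at its
#'   individually placed edge (a near-optimal start) instead of an NJ
#'   tree over imputed distances.
#' @return a support-annotated \code{phylo} over core taxa and duplicated
#'   entries.
#' @export
expanded_inference <- function(core, group, aln, scheme, seed = NULL,
                               supports = "abayes", B = 200L,
                               placements = NULL) {
  if (!length(group)) return(core$tree)
  entries <- make_duplicates(aln, scheme, group)
  mat <- aln$mat[core$core_taxa, , drop = FALSE]
  for (en in entries)
    mat <- rbind(mat, matrix(en$seq, 1L, ncol(mat),
                             dimnames = list(en$label, NULL)))
  ex_aln <- alignment(mat)
  start <- NULL
  if (!is.null(placements) &&
      all(vapply(entries, `[[`, "", "label") %in% names(placements)))
    start <- expanded_start(core$tree, entries, placements)
  infer_tree(ex_aln, scheme, regions = class_regions(scheme),
             models = core$models, supports = supports, B = B, seed = seed,
             start = start)
}

# graft every entry at its individually placed edge to seed the expanded
# search
expanded_start <- function(core_tree, entries, placements) {
  tr <- eng_tree(core_tree)
  core_taxa <- tr$tip.label
  for (en in entries) {
    p <- placements[[en$label]]
    key_tips <- strsplit(p$best_edge, "|", fixed = TRUE)[[1L]]
    clades <- edge_clades(tr)
    hit <- which(vapply(clades, function(cl)
      setequal(intersect(cl, core_taxa), key_tips), TRUE))
    if (!length(hit)) hit <- seq_len(nrow(tr$edge))
    e <- hit[order(lengths(clades[hit]))][1L]
    tr <- attach_tip(tr, e, en$label,
                     pendant = max(p$pendant_length, 1e-4))
  }
  tr
}
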