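# Phase 1: detection of hard topological incongruence between the
# nuclear-class and plastid-class trees, and attribution of conflicts to
# individual specimens by greedy leave-one-out testing.

#' Strongly supported non-trivial splits of an annotated tree
#'
#' A split passes under mode \code{"or"} if either support reaches its
#' threshold (the inspection rule "aBayes >= 0.95 and/or BS >= 95"), and
#' under \code{"and"} if both do.  A missing support type fails its
#' criterion.
#'
#' @param tree a support-annotated \code{phylo}.
#' @param mode \code{"or"} or \code{"and"}.
#' @param bs_min bootstrap threshold (percent).
#' @param ab_min aBayes threshold.
#' @param klass optional class tag attached to the returned splits.
#' @return list of split records (see \code{\link{tree_splits}}).
#' @export
strong_splits <- function(tree, mode = c("or", "and"), bs_min = 95,
                          ab_min = 0.95, klass = NA_character_) {
  mode <- match.arg(mode)
  splits <- tree_splits(tree, klass = klass)
  if (!length(splits)) return(splits)
  has_any <- any(vapply(splits, function(s) !is.na(s$bs) || !is.na(s$ab), TRUE))
  if (!has_any) {
    warning("tree has no support annotations; no strong splits")
    return(list())
  }
  keep <- vapply(splits, function(s) {
    bs_ok <- !is.na(s$bs) && s$bs >= bs_min
    ab_ok <- !is.na(s$ab) && s$ab >= ab_min
    if (mode == "or") bs_ok || ab_ok else bs_ok && ab_ok
  }, TRUE)
  splits[keep]
}

#' Are two splits incompatible on a shared taxon set?
#'
#' Standard split-compatibility criterion: restricted to the shared taxa,
#' splits A|B and C|D conflict iff all four intersections A∩C, A∩D, B∩C,
#' B∩D are non-empty (equivalently, no single tree can display both).
#' Trivial restrictions (a side with fewer than 2 shared taxa) are never
#' incompatible.
#'
#' @param a,b split records (fields \code{side}, \code{universe}).
#' @param shared taxon set to restrict to (default: intersection of the
#'   two universes).
#' @return logical.
#' @export
incompatible <- function(a, b, shared = NULL) {
  if (is.null(shared)) shared <- intersect(a$universe, b$universe)
  A <- intersect(a$side, shared); B <- setdiff(shared, A)
  C <- intersect(b$side, shared); D <- setdiff(shared, C)
  if (length(A) < 2L || length(B) < 2L || length(C) < 2L || length(D) < 2L)
    return(FALSE)
  length(intersect(A, C)) > 0L && length(intersect(A, D)) > 0L &&
    length(intersect(B, C)) > 0L && length(intersect(B, D)) > 0L
}

# ordering/reporting support of a single split: best of its two supports on
# a common [0,1] scale
split_score <- function(s) {
  max(c(if (!is.na(s$bs)) s$bs / 100, if (!is.na(s$ab)) s$ab, 0))
}

#' Detect hard conflicts between the nuclear and plastid trees
#'
#' All pairs of strongly supported splits (one from each class tree) that
#' are incompatible on the shared taxon set.  Records are ordered by the
#' minimum support of the pair (descending), then lexicographically.
#'
#' @param t_nuc,t_pla support-annotated class trees.
#' @param mode,bs_min,ab_min strong-support rule (see
#'   \code{\link{strong_splits}}).
#' @return list of class \code{"dup_conflicts"}; each record has the two
#'   splits, the shared taxa, the four intersection blocks and
#'   \code{min_support}.
#' @export
detect_hard_conflicts <- function(t_nuc, t_pla, mode = "or", bs_min = 95,
                                  ab_min = 0.95) {
  shared <- intersect(t_nuc$tip.label, t_pla$tip.label)
  if (length(shared) < 4L) stop("trees share fewer than 4 taxa")
  sn <- strong_splits(t_nuc, mode, bs_min, ab_min, klass = "nuclear")
  sp <- strong_splits(t_pla, mode, bs_min, ab_min, klass = "plastid")
  out <- list()
  for (a in sn) for (b in sp) {
    if (!incompatible(a, b, shared)) next
    A <- intersect(a$side, shared); B <- setdiff(shared, A)
    C <- intersect(b$side, shared); D <- setdiff(shared, C)
    out[[length(out) + 1L]] <- list(
      split_nuclear = a, split_plastid = b, shared = sort(shared),
      blocks = list(sort(intersect(A, C)), sort(intersect(A, D)),
                    sort(intersect(B, C)), sort(intersect(B, D))),
      min_support = min(split_score(a), split_score(b)))
  }
  if (length(out)) {
    keys <- vapply(out, conflict_key, "")
    ord <- order(-vapply(out, `[[`, 0, "min_support"), keys)
    out <- out[ord]
    for (i in seq_along(out)) out[[i]]$id <- paste0("C", i)
  }
  structure(out, class = "dup_conflicts")
}

#' @export
print.dup_conflicts <- function(x, ...) {
  cat(sprintf("%d hard conflict(s)\n", length(x)))
  for (cf in x)
    cat(sprintf("  %s: ITS %s | plastid %s (min support %.3f)\n", cf$id,
                paste(cf$split_nuclear$side, collapse = ","),
                paste(cf$split_plastid$side, collapse = ","),
                cf$min_support))
  invisible(x)
}

# identity key of a conflict, optionally restricted to a taxon subset;
# returns NA if either restricted split becomes trivial
conflict_key <- function(cf, taxa = cf$shared) {
  ra <- intersect(cf$split_nuclear$side, taxa)
  rb <- intersect(cf$split_plastid$side, taxa)
  if (length(ra) < 2L || length(setdiff(taxa, ra)) < 2L ||
      length(rb) < 2L || length(setdiff(taxa, rb)) < 2L) return(NA_character_)
  paste(split_key(ra, taxa), split_key(rb, taxa), sep = " ~ ")
}

# leave-one-out candidates: taxa appearing in a minimal intersection block
# of at least one conflict
minority_candidates <- function(conflicts) {
  cand <- character(0)
  for (cf in conflicts) {
    sizes <- lengths(cf$blocks)
    cand <- c(cand, unlist(cf$blocks[sizes == min(sizes)]))
  }
  sort(unique(cand))
}

# number of conflicts in whose minimal blocks each candidate appears
# (involvement; used to order leave-one-out evaluations)
candidate_involvement <- function(conflicts, cand) {
  vapply(cand, function(x) sum(vapply(conflicts, function(cf) {
    sizes <- lengths(cf$blocks)
    x %in% unlist(cf$blocks[sizes == min(sizes)])
  }, TRUE)), 0L)
}

#' Attribute hard conflicts to specimens by greedy leave-one-out testing
#'
#' Candidate specimens are those in a minimal intersection block of at
#' least one conflict.  Each candidate is removed in turn, both class
#' trees are re-inferred (reusing the per-region models of the full data)
#' and conflicts re-detected; the specimen resolving the most conflicts is
#' flagged (ties broken lexicographically) and the loop repeats until no
#' hard conflict remains or no candidate resolves anything (reported as
#' unattributable, never forced).
#'
#' @param aln,scheme data and partitions.
#' @param conflicts a \code{dup_conflicts} from the full class trees.
#' @param t_nuc,t_pla the full-data class trees.
#' @param seed integer seed (bootstrap resampling inside re-inference).
#' @param mode,bs_min,ab_min strong-support rule.
#' @param models_nuc,models_pla per-region models (default: taken from the
#'   \code{"models"} attribute of the class trees).
#' @param rates_nuc,rates_pla fixed per-region rate multipliers reused from
#'   the full-data class trees.
#' @param supports support type used for the re-inferred trees.
#' @param B bootstrap replicates when \code{supports} includes bootstrap.
#' @return list of class \code{"dup_flags"}: \code{flags} data frame
#'   (label, verdict, conflicts_resolved), \code{removed} in removal
#'   order, \code{converged}, \code{unattributable} conflict ids, and the
#'   final reduced class \code{trees}.
#' @export
attribute_specimens <- function(aln, scheme, conflicts, t_nuc, t_pla,
                                seed = NULL, mode = "or", bs_min = 95,
                                ab_min = 0.95,
                                models_nuc = attr(t_nuc, "models"),
                                models_pla = attr(t_pla, "models"),
                                rates_nuc = attr(t_nuc, "rates"),
                                rates_pla = attr(t_pla, "rates"),
                                supports = "abayes", B = 200L) {
  taxa <- intersect(t_nuc$tip.label, t_pla$tip.label)
  seeds <- derive_seeds(seed, 2L * length(taxa) + 2L)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[[si]] }
  reinfer <- function(keep, cur_nuc, cur_pla) {
    sub <- subset_alignment(aln, taxa = keep)
    # warm start: current class tree restricted to the kept taxa (the NNI
    # search still re-evaluates every move on the reduced data)
    tn <- infer_tree(sub, scheme, klass = "nuclear", models = models_nuc,
                     rates = rates_nuc, supports = supports, B = B,
                     seed = next_seed(), start = restrict_tree(cur_nuc, keep))
    tp <- infer_tree(sub, scheme, klass = "plastid", models = models_pla,
                     rates = rates_pla, supports = supports, B = B,
                     seed = next_seed(), start = restrict_tree(cur_pla, keep))
    list(nuc = tn, pla = tp,
         conflicts = detect_hard_conflicts(tn, tp, mode, bs_min, ab_min))
  }
  removed <- character(0)
  resolved_by <- list()
  cur <- list(nuc = t_nuc, pla = t_pla, conflicts = conflicts)
  converged <- TRUE
  unattributable <- character(0)
  # score of removing a unit (one specimen, or a whole minimal block when
  # no single removal helps): net reduction in the hard-conflict count.
  # Conflicts whose restriction merely becomes trivial are not credited —
  # removing a bystander that sits in a small block trivializes splits
  # without resolving the underlying discordance.
  eval_unit <- function(unit, keep_now) {
    keep <- setdiff(keep_now, unit)
    if (length(keep) < 4L) return(list(score = -Inf))
    res <- reinfer(keep, cur$nuc, cur$pla)
    before <- vapply(cur$conflicts, conflict_key,
                     taxa = intersect(cur$conflicts[[1L]]$shared, keep), "")
    after <- vapply(res$conflicts, conflict_key, "")
    before_ids <- vapply(cur$conflicts, `[[`, "", "id")
    list(score = sum(!is.na(before)) - length(res$conflicts), res = res,
         resolved = before_ids[!is.na(before) & !(before %in% after)])
  }
  while (length(cur$conflicts)) {
    cand <- setdiff(minority_candidates(cur$conflicts), removed)
    if (!length(cand)) { converged <- FALSE; break }
    keep_now <- setdiff(taxa, removed)
    # singletons first, lazily, in decreasing involvement order; stop when
    # no unevaluated candidate's involvement bound can beat the best score
    inv <- candidate_involvement(cur$conflicts, cand)
    cand <- cand[order(-inv, cand)]
    inv <- inv[cand]
    best <- NULL; best_score <- 0L; evaluated <- list()
    zero_found <- FALSE
    for (ci in seq_along(cand)) {
      ev <- eval_unit(cand[ci], keep_now)
      evaluated[[cand[ci]]] <- ev
      if (is.finite(ev$score) && ev$score > best_score) {
        best <- cand[ci]; best_score <- ev$score
        zero_found <- length(ev$res$conflicts) == 0L
      }
      if (zero_found) break
      if (ci < length(cand) && best_score >= max(inv[(ci + 1L):length(cand)]))
        break
    }
    if (!zero_found) {
      # no single specimen reaches a conflict-free state: hybrids that
      # travel as a block (e.g. sisters sharing both donors) are only
      # separable jointly — also test removal of whole minimal blocks
      blocks <- list()
      for (cf in cur$conflicts) {
        sizes <- lengths(cf$blocks)
        for (b in cf$blocks[sizes == min(sizes)])
          if (length(b) >= 2L && length(b) <= 4L) {
            key <- paste(sort(b), collapse = "+")
            blocks[[key]] <- (blocks[[key]] %||% 0L) + 1L
          }
      }
      if (length(blocks)) {
        freq <- unlist(blocks)
        keys <- names(freq)[order(-freq,
                                  lengths(strsplit(names(freq), "+",
                                                   fixed = TRUE)),
                                  names(freq))]
        for (key in utils::head(keys, 5L)) {
          unit <- strsplit(key, "+", fixed = TRUE)[[1L]]
          if (all(unit %in% removed)) next
          ev <- eval_unit(unit, keep_now)
          evaluated[[key]] <- ev
          if (is.finite(ev$score) && ev$score > best_score) {
            best <- key; best_score <- ev$score
          }
          if (length(ev$res$conflicts) == 0L &&
              is.finite(ev$score) && ev$score > 0L) break
        }
      }
    }
    if (is.null(best)) {
      converged <- FALSE
      unattributable <- vapply(cur$conflicts, `[[`, "", "id")
      break
    }
    unit <- strsplit(best, "+", fixed = TRUE)[[1L]]
    removed <- c(removed, unit)
    for (x in unit) resolved_by[[x]] <- evaluated[[best]]$resolved
    cur <- evaluated[[best]]$res
  }
  if (length(cur$conflicts) && converged == TRUE) converged <- FALSE
  flags <- data.frame(
    label = taxa,
    verdict = ifelse(taxa %in% removed, "incongruent", "congruent"),
    conflicts_resolved = vapply(taxa, function(x)
      paste(resolved_by[[x]], collapse = ","), ""))
  structure(list(flags = flags, removed = removed, converged = converged,
                 unattributable = unattributable, trees = cur[c("nuc", "pla")],
                 remaining_conflicts = cur$conflicts),
            class = "dup_flags")
}

#' @export
print.dup_flags <- function(x, ...) {
  cat(sprintf("%d specimen(s) flagged incongruent: %s\n", length(x$removed),
              paste(x$removed, collapse = ", ")))
  if (!x$converged)
    cat("WARNING: conflicts remain unattributed:",
        paste(x$unattributable, collapse = ", "), "\n")
  invisible(x)
}
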