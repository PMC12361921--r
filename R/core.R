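# Phase 1 output: the core dataset (congruent specimens only) and the
# combined-data core tree.

#' Build the core phylogeny
#'
#' Drops the flagged (incongruent) specimens, verifies that the reduced
#' class trees exhibit zero hard conflicts (hard failure otherwise — data
#' are only ever combined when congruent), and infers the combined-data
#' core tree over all regions with dual supports.
#'
#' @param aln,scheme data and partitions.
#' @param flags a \code{dup_flags} from \code{\link{attribute_specimens}},
#'   a character vector of specimen labels to exclude, or NULL when no
#'   conflicts were detected (core = full dataset).
#' @param seed integer seed.
#' @param models named per-region model list (NULL: select).
#' @param verify re-check the zero-conflict invariant on the reduced class
#'   trees (skipped when \code{flags} already carries the reduced trees
#'   for exactly the core taxon set).
#' @param mode,bs_min,ab_min strong-support rule for verification.
#' @param supports,B support annotation for the core tree.
#' @return list of class \code{"dup_core"}: \code{core_taxa},
#'   \code{excluded} (with reasons), \code{tree}, \code{models},
#'   \code{class_trees}.
#' @export
build_core <- function(aln, scheme, flags = NULL, seed = NULL, models = NULL,
                       verify = TRUE, mode = "or", bs_min = 95,
                       ab_min = 0.95, supports = "both", B = 200L) {
  removed <- if (is.null(flags)) character(0)
             else if (inherits(flags, "dup_flags")) flags$removed
             else as.character(flags)
  core_taxa <- setdiff(aln$taxa, removed)
  if (length(core_taxa) < 4L)
    stop("fewer than 4 congruent taxa remain; cannot build a core tree")
  seeds <- derive_seeds(seed, 3L)
  class_trees <- NULL
  if (inherits(flags, "dup_flags") &&
      setequal(flags$trees$nuc$tip.label, core_taxa)) {
    class_trees <- flags$trees
    residual <- flags$remaining_conflicts
  } else if (verify) {
    sub <- subset_alignment(aln, taxa = core_taxa)
    tn <- infer_tree(sub, scheme, klass = "nuclear", models = models,
                     supports = "abayes", seed = seeds[[1L]])
    tp <- infer_tree(sub, scheme, klass = "plastid", models = models,
                     supports = "abayes", seed = seeds[[2L]])
    class_trees <- list(nuc = tn, pla = tp)
    residual <- detect_hard_conflicts(tn, tp, mode, bs_min, ab_min)
  } else residual <- list()
  if (length(residual))
    stop("hard conflict remains among core taxa (", residual[[1L]]$id,
         ": ITS ", paste(residual[[1L]]$split_nuclear$side, collapse = ","),
         " vs plastid ", paste(residual[[1L]]$split_plastid$side,
                               collapse = ","),
         "); refusing to combine incongruent data")
  sub <- subset_alignment(aln, taxa = core_taxa)
  tree <- infer_tree(sub, scheme, regions = class_regions(scheme),
                     models = models, supports = supports, B = B,
                     seed = seeds[[3L]])
  excluded <- data.frame(label = removed,
                         reason = rep("incongruent (hard ITS/plastid conflict)",
                                      length(removed)))
  structure(list(core_taxa = sort(core_taxa), excluded = excluded,
                 tree = tree, models = attr(tree, "models"),
                 rates = attr(tree, "rates"), class_trees = class_trees),
            class = "dup_core")
}

#' @export
print.dup_core <- function(x, ...) {
  cat(sprintf("Core phylogeny: %d taxa (%d excluded)\n",
              length(x$core_taxa), nrow(x$excluded)))
  invisible(x)
}
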