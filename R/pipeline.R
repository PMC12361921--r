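# End-to-end orchestration of the three phases, with a manifest of seeds,
# thresholds and output checksums for reproducibility auditing.

#' Run configuration for the three-phase pipeline
#'
#' @param alignment path to a FASTA alignment, or a \code{dup_alignment}.
#' @param partitions path to a partition config, or a
#'   \code{dup_partitions}.
#' @param outdir output directory.
#' @param bs_min,ab_min,mode strong-support thresholds and combination
#'   rule ("or" matches the inspection phrase "aBayes >= 0.95 and/or
#'   BS >= 95%").
#' @param B bootstrap replicates (desk-scale default 200; raise toward
#'   10000 for publication-grade supports).
#' @param candidates substitution-model candidate labels.
#' @param supports support annotation for class/core trees:
#'   \code{"both"}, \code{"abayes"}, \code{"bootstrap"}.
#' @param clades optional named clade list for pattern labelling.
#' @param seed master integer seed; every stochastic stage receives a
#'   deterministic child seed.
#' @return list of class \code{"dup_runconfig"}.
#' @export
run_config <- function(alignment, partitions, outdir = "phylodup_run",
                       bs_min = 95, ab_min = 0.95, mode = "or", B = 200L,
                       candidates = model_candidates(gamma_only = TRUE),
                       supports = "both", clades = NULL, seed = 1L) {
  stopifnot(bs_min >= 0, bs_min <= 100, ab_min >= 0, ab_min <= 1, B >= 1L)
  structure(list(alignment = alignment, partitions = partitions,
                 outdir = outdir, bs_min = bs_min, ab_min = ab_min,
                 mode = mode, B = as.integer(B), candidates = candidates,
                 supports = supports, clades = clades,
                 seed = as.integer(seed)),
            class = "dup_runconfig")
}

stage_log <- function(run, stage, t0, ...) {
  msg <- sprintf("[%s] %s (%.1fs) %s", format(Sys.time(), "%H:%M:%S"), stage,
                 as.numeric(Sys.time()) - t0, paste(..., collapse = " "))
  message(msg)
  c(run, msg)
}

#' Run the full three-phase analysis
#'
#' Phase 1: per-class trees with dual supports, hard-conflict scan,
#' specimen attribution, core phylogeny.  Phase 2: taxon duplication,
#' individual placement of every entry against the core tree, expanded
#' inference per discordance-pattern group.  Phase 3: pattern
#' classification and floating-ITS-group detection.  All tables and trees
#' are written under \code{config$outdir} together with a manifest
#' (thresholds, seeds, file checksums); re-running the same config
#' reproduces identical outputs.
#'
#' @param config a \code{dup_runconfig}.
#' @return invisible list with all intermediate results.
#' @export
run_all <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  aln <- if (inherits(config$alignment, "dup_alignment")) config$alignment
         else read_alignment(config$alignment)
  scheme <- if (inherits(config$partitions, "dup_partitions")) config$partitions
            else read_partitions(config$partitions, aln$n_columns)
  seeds <- derive_seeds(config$seed, 8L)
  log <- character(0); t0 <- as.numeric(Sys.time())

  # ---- phase 1: class trees, conflict scan, core ----
  t_nuc <- infer_tree(aln, scheme, klass = "nuclear",
                      candidates = config$candidates,
                      supports = config$supports, B = config$B,
                      seed = seeds[[1L]])
  t_pla <- infer_tree(aln, scheme, klass = "plastid",
                      candidates = config$candidates,
                      supports = config$supports, B = config$B,
                      seed = seeds[[2L]])
  write_tree_file(t_nuc, file.path(config$outdir, "tree_nuclear.nwk"))
  write_tree_file(t_pla, file.path(config$outdir, "tree_plastid.nwk"))
  log <- stage_log(log, "phase1/class-trees", t0,
                   sprintf("lnL nuc %.2f pla %.2f", attr(t_nuc, "loglik"),
                           attr(t_pla, "loglik")))

  conflicts <- detect_hard_conflicts(t_nuc, t_pla, config$mode,
                                     config$bs_min, config$ab_min)
  write_conflict_table(conflicts, file.path(config$outdir, "conflicts.tsv"))
  if (length(conflicts)) {
    fl <- attribute_specimens(aln, scheme, conflicts, t_nuc, t_pla,
                              seed = seeds[[3L]], mode = config$mode,
                              bs_min = config$bs_min, ab_min = config$ab_min)
  } else {
    fl <- structure(list(flags = data.frame(label = aln$taxa,
                                            verdict = "congruent",
                                            conflicts_resolved = ""),
                         removed = character(0), converged = TRUE,
                         unattributable = character(0),
                         trees = list(nuc = t_nuc, pla = t_pla),
                         remaining_conflicts = list()),
                    class = "dup_flags")
  }
  utils::write.table(fl$flags, file.path(config$outdir, "specimen_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- stage_log(log, "phase1/conflict-scan", t0,
                   sprintf("%d conflicts, %d flagged", length(conflicts),
                           length(fl$removed)))

  core <- build_core(aln, scheme, if (length(fl$removed)) fl else NULL,
                     seed = seeds[[4L]], supports = config$supports,
                     B = config$B, mode = config$mode,
                     bs_min = config$bs_min, ab_min = config$ab_min)
  write_tree_file(core$tree, file.path(config$outdir, "core_tree.nwk"))
  utils::write.table(core$excluded, file.path(config$outdir, "excluded.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_model_table(core, scheme, file.path(config$outdir, "model_table.tsv"))
  log <- stage_log(log, "phase1/core", t0,
                   sprintf("core %d taxa", length(core$core_taxa)))

  # ---- phase 2: duplication, placement, expanded inference ----
  placements <- list(); patterns <- NULL; groups <- list()
  expanded <- list(); floating <- list()
  clmap <- clade_map(core, config$clades, config$mode, config$bs_min,
                     config$ab_min)
  if (length(fl$removed)) {
    entries <- make_duplicates(aln, scheme, fl)
    ind <- analyze_individually(entries, core, aln, scheme, clades = clmap,
                                seed = seeds[[5L]])
    placements <- ind$placements; patterns <- ind$patterns
    groups <- ind$groups
    write_placement_table(placements,
                          file.path(config$outdir, "placements.tsv"))
    log <- stage_log(log, "phase2/placement", t0,
                     sprintf("%d entries placed", length(placements)))
    gseeds <- derive_seeds(seeds[[6L]], length(groups) + 1L)
    for (g in seq_along(groups)) {
      ex <- expanded_inference(core, groups[[g]], aln, scheme,
                               seed = gseeds[[g]], placements = placements)
      expanded[[names(groups)[g]]] <- ex
      write_tree_file(ex, file.path(config$outdir,
                                    sprintf("expanded_group%d.nwk", g)))
    }
    # joint overall phylogeny with every flagged specimen: floating ITS
    # groups span pattern groups (shared ITS side, divergent plastid
    # sides), so they are sought here
    ex_all <- if (length(groups) == 1L) expanded[[1L]]
              else expanded_inference(core, fl$removed, aln, scheme,
                                      seed = gseeds[[length(groups) + 1L]],
                                      placements = placements)
    expanded[["overall"]] <- ex_all
    write_tree_file(ex_all, file.path(config$outdir, "expanded_overall.nwk"))
    floating <- find_floating_groups(ex_all, placements, clmap, core,
                                     config$mode, config$bs_min,
                                     config$ab_min)
    log <- stage_log(log, "phase2/expanded", t0,
                     sprintf("%d group(s)", length(groups)))
  }

  # ---- phase 3: pattern tables ----
  if (!is.null(patterns))
    utils::write.table(patterns, file.path(config$outdir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_floating_table(floating, file.path(config$outdir,
                                           "floating_groups.tsv"))
  log <- stage_log(log, "phase3/classify", t0,
                   sprintf("%d pattern group(s), %d floating group(s)",
                           length(groups), length(floating)))

  manifest <- c(
    sprintf("seed = %d", config$seed),
    sprintf("bs_min = %g; ab_min = %g; mode = %s", config$bs_min,
            config$ab_min, config$mode),
    sprintf("B = %d; supports = %s", config$B, config$supports),
    sprintf("candidates = %s", paste(config$candidates, collapse = ",")),
    "checksums:",
    {
      fs <- sort(setdiff(list.files(config$outdir), "manifest.txt"))
      paste0("  ", fs, " md5=", tools::md5sum(file.path(config$outdir, fs)))
    })
  writeLines(manifest, file.path(config$outdir, "manifest.txt"))
  writeLines(log, file.path(config$outdir, "run_log.txt"))
  invisible(list(config = config, aln = aln, scheme = scheme,
                 class_trees = list(nuc = t_nuc, pla = t_pla),
                 conflicts = conflicts, flags = fl, core = core,
                 placements = placements, patterns = patterns,
                 groups = groups, expanded = expanded, floating = floating,
                 clades = clmap))
}

write_conflict_table <- function(conflicts, path) {
  if (!length(conflicts)) {
    writeLines("id\tnuclear_side\tplastid_side\tmin_support", path)
    return(invisible(path))
  }
  tab <- do.call(rbind, lapply(conflicts, function(cf)
    data.frame(id = cf$id,
               nuclear_side = paste(cf$split_nuclear$side, collapse = ","),
               plastid_side = paste(cf$split_plastid$side, collapse = ","),
               min_support = cf$min_support)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_placement_table <- function(placements, path) {
  tab <- do.call(rbind, lapply(placements, function(p)
    data.frame(entry = p$label, parent = p$parent, klass = p$klass,
               best_edge = p$best_edge, lwr = max(p$lwr$lwr),
               pendant = p$pendant_length, loglik = p$loglik)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_floating_table <- function(floating, path) {
  if (!length(floating)) {
    writeLines("members\tbs\tab\tplastid_clades", path)
    return(invisible(path))
  }
  tab <- do.call(rbind, lapply(floating, function(g)
    data.frame(members = paste(g$members, collapse = ","),
               bs = g$support["bs"], ab = g$support["ab"],
               plastid_clades = paste(g$plastid_clades, collapse = ","))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_model_table <- function(core, scheme, path) {
  regions <- class_regions(scheme)
  tab <- data.frame(
    region = regions,
    klass = region_classes(scheme)[regions],
    characters = vapply(regions, function(nm)
      length(region_columns(scheme, nm)), 0L),
    model = vapply(regions, function(nm) {
      m <- core$models[[nm]]
      sprintf("%s%s", m$name,
              if (!is.null(m$gamma_shape)) sprintf("+G%d", m$n_cat) else "")
    }, ""),
    rate = if (!is.null(core$rates)) core$rates[regions] else NA_real_)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a completed (or partial) run directory
#'
#' @param dir a run directory written by \code{\link{run_all}}.
#' @return invisible list of the parsed tables; prints a human-readable
#'   summary.
#' @export
report <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.delim(p) else NULL
  }
  flags <- rd("specimen_flags.tsv"); conf <- rd("conflicts.tsv")
  excl <- rd("excluded.tsv"); pat <- rd("patterns.tsv")
  flo <- rd("floating_groups.tsv"); mod <- rd("model_table.tsv")
  cat("== phylodup run summary:", dir, "==\n")
  if (is.null(flags)) { cat("no stages found\n"); return(invisible(NULL)) }
  cat(sprintf("specimens: %d (%d congruent, %d incongruent)\n", nrow(flags),
              sum(flags$verdict == "congruent"),
              sum(flags$verdict == "incongruent")))
  if (!is.null(conf)) cat(sprintf("hard conflicts: %d\n", nrow(conf)))
  if (!is.null(excl) && nrow(excl))
    cat("excluded from core:", paste(excl$label, collapse = ", "), "\n")
  if (!is.null(mod)) {
    cat("per-region models:\n")
    print(mod, row.names = FALSE)
  }
  if (!is.null(pat) && nrow(pat)) {
    cat("discordance patterns (PL / ITS placements):\n")
    print(pat, row.names = FALSE)
  } else cat("discordance patterns: not run\n")
  if (!is.null(flo))
    cat(sprintf("floating ITS groups: %d\n",
                sum(nzchar(flo$members %||% character(0)))))
  invisible(list(flags = flags, conflicts = conf, excluded = excl,
                 patterns = pat, floating = flo, models = mod))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
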