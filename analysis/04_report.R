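#!/usr/bin/env Rscript
# Human-readable summary of the completed run in results/run/: core size,
# excluded specimens, per-region models, the PL/ITS discordance pattern of
# every flagged specimen, and any floating ITS groups.

library(phylodup)

run_dir <- file.path("results", "run")
if (!dir.exists(run_dir))
  stop("run analysis/02_run_phases.R first")

report(run_dir)

fg <- utils::read.delim(file.path(run_dir, "floating_groups.tsv"))
if (nrow(fg)) {
  cat("\nFloating ITS groups (homogenized nuclear copies whose plastid\n")
  cat("partners attach to divergent lineages):\n")
  print(fg, row.names = FALSE)
}
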