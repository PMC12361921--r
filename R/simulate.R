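# Synthetic benchmark generator: Yule species trees, planted hybridization
# events (tip regrafting between donor lineages, emulating chloroplast
# capture / ITS homogenization), sequence evolution along the per-class
# gene trees, and ground-truth tables for recovery testing.

#' Simulation configuration
#'
#' Defaults describe the benchmark scenario used throughout the package
#' tests: 24 taxa, 2 planted hybrids whose plastid and ITS donor edges are
#' at least 4 edges apart, four plastid regions of 500 bp and one nuclear
#' (ITS) region of 800 bp, GTR+G sequences, tree height 0.3 expected
#' substitutions/site.
#'
#' @param n_taxa number of species (>= 4).
#' @param lambda Yule birth rate (per lineage).
#' @param height root-to-tip depth of the scaled species tree, in expected
#'   substitutions/site (NULL: keep raw Yule time units).
#' @param n_hybrids number of planted hybrid taxa (<= n_taxa / 4).
#' @param donor_min_dist minimum edge-graph distance between a hybrid's
#'   plastid and ITS donor edges.
#' @param shared_donors if TRUE all hybrids share one plastid donor edge and
#'   one ITS donor edge (a single discordance pattern); if FALSE each hybrid
#'   draws its own donors.
#' @param share_its,share_plastid finer control (override
#'   \code{shared_donors}): share only the ITS or only the plastid donor.
#' @param regions data frame with columns \code{name}, \code{klass},
#'   \code{length}, \code{rate} describing the simulated regions.
#' @param model a \code{dup_model} used to evolve sequences.
#' @param root_freqs root state composition.
#' @param missing_frac fraction of (taxon, region) cells masked to
#'   \code{?} (whole-region missing data).
#' @param seed mandatory integer seed.
#' @return list of class \code{"dup_simconfig"}.
#' @export
sim_config <- function(n_taxa = 24L, lambda = 1, height = 0.3,
                       n_hybrids = 2L, donor_min_dist = 4L,
                       shared_donors = FALSE,
                       share_its = shared_donors,
                       share_plastid = shared_donors,
                       regions = data.frame(
                         name = c("pl_rps16_trnK", "pl_rps16", "pl_rpl32_trnL",
                                  "pl_ndhA", "ITS"),
                         klass = c(rep("plastid", 4L), "nuclear"),
                         length = c(500L, 500L, 500L, 500L, 800L),
                         rate = c(1, 1, 1, 1, 2)),
                       model = substitution_model("GTR",
                         freqs = c(0.3, 0.2, 0.2, 0.3),
                         rates = c(1.5, 3, 0.5, 0.8, 2.5, 1),
                         gamma_shape = 0.8),
                       root_freqs = model$freqs,
                       missing_frac = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory (reproducibility)")
  if (n_hybrids > n_taxa / 4) stop("n_hybrids must be <= n_taxa / 4")
  if (any(regions$length < 100L)) stop("region lengths must be >= 100")
  structure(list(n_taxa = as.integer(n_taxa), lambda = lambda,
                 height = height, n_hybrids = as.integer(n_hybrids),
                 donor_min_dist = as.integer(donor_min_dist),
                 share_its = share_its, share_plastid = share_plastid,
                 regions = regions, model = model, root_freqs = root_freqs,
                 missing_frac = missing_frac, seed = as.integer(seed)),
            class = "dup_simconfig")
}

#' Simulate a Yule species tree
#'
#' Forward pure-birth simulation: two lineages at time zero, each splitting
#' at rate \code{lambda}, stopped when \code{n} tips exist (tips extend to
#' the drawn time of the next, unrealized, split).  Optionally rescaled so
#' the root-to-tip depth equals \code{height} expected substitutions/site.
#'
#' @param n number of tips (>= 4).
#' @param lambda birth rate.
#' @param seed integer seed.
#' @param height target depth in substitutions/site (NULL: raw time units).
#' @return a rooted, ultrametric \code{phylo} with tips \code{t1..tn}.
#' @export
simulate_species_tree <- function(n, lambda = 1, seed = NULL, height = NULL) {
  if (n < 4L) stop("need n >= 4 taxa")
  if (lambda <= 0) stop("lambda must be positive")
  with_seed_(seed, {
    # active lineages record (parent node id, birth time); internal node
    # ids are assigned in birth order so parents always precede children
    nid <- n + 1L
    act_parent <- c(nid, nid); act_birth <- c(0, 0)
    t_cur <- 0
    edges <- NULL    # (parent, child, length) for internal children
    nxt <- n + 2L
    while (length(act_parent) < n) {
      k <- length(act_parent)
      t_cur <- t_cur + stats::rexp(1L, k * lambda)
      i <- sample.int(k, 1L)
      edges <- rbind(edges, c(act_parent[i], nxt, t_cur - act_birth[i]))
      act_parent <- c(act_parent[-i], nxt, nxt)
      act_birth <- c(act_birth[-i], t_cur, t_cur)
      nxt <- nxt + 1L
    }
    t_end <- t_cur + stats::rexp(1L, n * lambda)
    tips <- sample.int(n, n)   # random assignment of tip numbers
    for (i in seq_len(n))
      edges <- rbind(edges, c(act_parent[i], tips[i], t_end - act_birth[i]))
    tree <- structure(list(edge = edges[, 1:2, drop = FALSE],
                           edge.length = edges[, 3L],
                           tip.label = paste0("t", seq_len(n)),
                           Nnode = n - 1L), class = "phylo")
    tree <- ape::reorder.phylo(tree, "postorder")
    if (!is.null(height)) tree$edge.length <- tree$edge.length * height / t_end
    tree
  })
}

# clade (tip set) below each edge of a rooted tree, as a list keyed by row
edge_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    v <- tree$edge[e, 2L]
    if (v <= ntip) tree$tip.label[v] else sort(tip_set(tree, v))
  })
}

# edge-graph distance matrix: edges are vertices, adjacent iff sharing a node
edge_graph_dist <- function(tree) {
  E <- nrow(tree$edge)
  adj <- matrix(FALSE, E, E)
  for (i in seq_len(E - 1L)) for (j in (i + 1L):E)
    adj[i, j] <- adj[j, i] <- length(intersect(tree$edge[i, ], tree$edge[j, ])) > 0L
  D <- matrix(Inf, E, E); diag(D) <- 0
  for (e in seq_len(E)) {     # BFS from each edge
    frontier <- e; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(apply(adj[, frontier, drop = FALSE], 1L, any) & is.infinite(D[e, ]))
      D[e, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# prune `tip` and regraft it onto the edge above clade `donor` (tip labels),
# attaching at the edge midpoint with an ultrametric pendant; `within`
# restricts clade matching (other hybrids still in the tree are ignored)
regraft_tip <- function(tree, tip, donor, within = NULL) {
  pruned <- ape::drop.tip(tree, tip)
  if (is.null(within)) within <- pruned$tip.label
  clades <- edge_clades(pruned)
  hit <- which(vapply(clades, function(cl)
    setequal(intersect(cl, within), donor), TRUE))
  if (!length(hit))
    stop("donor clade not found after pruning: ", paste(donor, collapse = ","))
  e <- hit[order(lengths(clades[hit]))][1L]
  depth <- ape::node.depth.edgelength(pruned)
  ntip <- length(pruned$tip.label)
  h_tree <- max(depth[seq_len(ntip)])
  # height (above present) of the attachment midpoint
  child <- pruned$edge[e, 2L]
  h_mid <- h_tree - (depth[child] - pruned$edge.length[e] / 2)
  att <- attach_tip(pruned, e, tip, pendant = max(h_mid, 1e-8), split_at = 0.5)
  att
}

# attach a new tip to edge row e of `tree`; the edge is split at fraction
# `split_at` from the parent end; returns a phylo whose old tips keep their
# numbers and whose new tip is ntip+1
attach_tip <- function(tree, e, label, pendant, split_at = 0.5) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  # shift internal ids by 1 to make room for the new tip number
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  newtip <- ntip + 1L
  newnode <- ntip + 1L + tree$Nnode + 1L
  u <- edge[e, 1L]; v <- edge[e, 2L]; l <- len[e]
  edge[e, ] <- c(u, newnode); len[e] <- l * split_at
  edge <- rbind(edge, c(newnode, v), c(newnode, newtip))
  len <- c(len, l * (1 - split_at), pendant)
  out <- structure(list(edge = edge, edge.length = len,
                        tip.label = c(tree$tip.label, label),
                        Nnode = tree$Nnode + 1L), class = "phylo")
  ape::reorder.phylo(out, "postorder")
}

#' Plant hybridization events into a species tree
#'
#' For each hybrid tip, the plastid gene tree is formed by pruning the tip
#' and regrafting it onto its plastid donor edge, and likewise the nuclear
#' gene tree onto its ITS donor edge (a clean "capture" model: gene trees
#' differ from the species tree exactly by the planted regrafts).  Donor
#' edges are drawn uniformly among internal+pendant edges subject to the
#' distance constraint; when donors are shared among hybrids, later hybrids
#' attach next to the earlier ones so their gene copies form a clade.
#'
#' @param species rooted species tree (\code{phylo}).
#' @param config a \code{dup_simconfig}.
#' @param seed integer seed (defaults to \code{config$seed + 1}).
#' @return list of class \code{"dup_truth"}: \code{species},
#'   \code{gene_trees} (plastid, nuclear), and per-hybrid donor records
#'   (\code{hybrids}: label, plastid_donor, its_donor as tip-set keys).
#' @export
plant_hybrids <- function(species, config, seed = config$seed + 1L) {
  nh <- config$n_hybrids
  with_seed_(seed, {
    ntip <- length(species$tip.label)
    hybrids <- sort(sample(species$tip.label, nh))
    # donors are edges of the species tree restricted to non-hybrids, so
    # they stay identifiable on the core tree
    backbone <- ape::drop.tip(species, hybrids)
    clades <- edge_clades(backbone)
    D <- edge_graph_dist(backbone)
    E <- nrow(backbone$edge)
    draw_pair <- function() {
      ok <- which(D >= config$donor_min_dist, arr.ind = TRUE)
      if (!nrow(ok)) stop("donor distance constraint unsatisfiable")
      pick <- as.integer(ok[sample.int(nrow(ok), 1L), ])
      c(pl = pick[1L], its = pick[2L])
    }
    pairs <- vector("list", nh)
    shared <- draw_pair()
    for (i in seq_len(nh)) {
      own <- draw_pair()
      pairs[[i]] <- c(pl = if (config$share_plastid) unname(shared["pl"]) else unname(own["pl"]),
                      its = if (config$share_its) unname(shared["its"]) else unname(own["its"]))
      # enforce the distance constraint for mixed shared/own draws
      tries <- 0L
      while (D[pairs[[i]]["pl"], pairs[[i]]["its"]] < config$donor_min_dist) {
        own <- draw_pair()
        pairs[[i]] <- c(pl = if (config$share_plastid) unname(shared["pl"]) else unname(own["pl"]),
                        its = if (config$share_its) unname(shared["its"]) else unname(own["its"]))
        tries <- tries + 1L
        if (tries > 200L) stop("donor distance constraint unsatisfiable")
      }
    }
    build_gene_tree <- function(which_donor) {
      gt <- species
      attached <- list()   # donor edge key -> label of last attached hybrid
      for (i in seq_len(nh)) {
        donor_edge <- pairs[[i]][[which_donor]]
        key <- paste(clades[[donor_edge]], collapse = "|")
        target <- if (!is.null(attached[[key]])) attached[[key]] else clades[[donor_edge]]
        gt <- regraft_tip(gt, hybrids[i], target,
                          within = union(backbone$tip.label, target))
        attached[[key]] <- hybrids[i]
      }
      gt
    }
    truth <- data.frame(
      label = hybrids,
      plastid_donor = vapply(pairs, function(p) paste(clades[[p["pl"]]], collapse = "|"), ""),
      its_donor = vapply(pairs, function(p) paste(clades[[p["its"]]], collapse = "|"), ""))
    structure(list(species = species, backbone = backbone,
                   gene_trees = list(plastid = build_gene_tree("pl"),
                                     nuclear = build_gene_tree("its")),
                   hybrids = truth, config = config),
              class = "dup_truth")
  })
}

# simulate states down a tree under `model`, site categories fixed per site
evolve_states <- function(tree, model, L, rate = 1, root_freqs = model$freqs) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  nodes <- n + tr$Nnode
  states <- matrix(0L, nodes, L)
  root <- n + 1L
  cat_idx <- sample.int(model$n_cat, L, replace = TRUE)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = root_freqs)
  for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    for (k in seq_len(model$n_cat)) {
      idx <- which(cat_idx == k)
      if (!length(idx)) next
      P <- transition_matrix(model, tr$edge.length[e] * rate,
                             model$cat_rates[k])
      cum <- t(apply(P, 1L, cumsum))
      u01 <- stats::runif(length(idx))
      states[v, idx] <- max.col(cum[states[u, idx], , drop = FALSE] >= u01,
                                "first")
    }
  }
  out <- matrix(STATE_ORDER[states[seq_len(n), , drop = FALSE]], n, L)
  rownames(out) <- tr$tip.label
  out
}

#' Evolve a concatenated two-class alignment along the gene trees
#'
#' Each region is simulated along its class's gene tree under the config
#' model, with the region's rate multiplier scaling all branch lengths and
#' site-specific gamma categories held constant across the tree.  Regions
#' are concatenated in config order and whole-region missing data is
#' masked as \code{?} at the configured fraction.
#'
#' @param truth a \code{dup_truth} from \code{\link{plant_hybrids}}.
#' @param config a \code{dup_simconfig}.
#' @param seed integer seed (defaults to \code{config$seed + 2}).
#' @return list: \code{aln} (\code{dup_alignment}), \code{scheme}
#'   (\code{dup_partitions}).
#' @export
evolve_alignment <- function(truth, config, seed = config$seed + 2L) {
  with_seed_(seed, {
    regs <- config$regions
    taxa <- sort(truth$species$tip.label)
    blocks <- vector("list", nrow(regs))
    start <- 1L
    part <- regs[, c("name", "klass")]
    part$start <- NA_integer_; part$end <- NA_integer_
    for (r in seq_len(nrow(regs))) {
      gt <- truth$gene_trees[[regs$klass[r]]]
      m <- evolve_states(gt, config$model, regs$length[r], rate = regs$rate[r],
                         root_freqs = config$root_freqs)
      blocks[[r]] <- m[taxa, , drop = FALSE]
      part$start[r] <- start; part$end[r] <- start + regs$length[r] - 1L
      start <- start + regs$length[r]
    }
    mat <- do.call(cbind, blocks)
    rownames(mat) <- taxa
    if (config$missing_frac > 0) {
      for (r in seq_len(nrow(regs))) {
        mask <- stats::runif(length(taxa)) < config$missing_frac
        mat[mask, part$start[r]:part$end[r]] <- "?"
      }
    }
    list(aln = alignment(mat), scheme = partition_scheme(part))
  })
}

#' Generate a complete on-disk benchmark bundle
#'
#' Composes \code{\link{simulate_species_tree}},
#' \code{\link{plant_hybrids}} and \code{\link{evolve_alignment}} and
#' writes a self-describing bundle: alignment FASTA, partition config,
#' truth table, species/gene trees and the echoed configuration.
#' Re-running with the same config is byte-identical.
#'
#' @param config a \code{dup_simconfig}.
#' @param dir output directory (created if needed); NULL returns the
#'   in-memory bundle without writing.
#' @return invisible list: \code{aln}, \code{scheme}, \code{truth},
#'   \code{dir}.
#' @export
make_benchmark <- function(config, dir = NULL) {
  species <- simulate_species_tree(config$n_taxa, config$lambda,
                                   seed = config$seed, height = config$height)
  truth <- plant_hybrids(species, config)
  ev <- evolve_alignment(truth, config)
  bundle <- list(aln = ev$aln, scheme = ev$scheme, truth = truth, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_alignment(ev$aln, file.path(dir, "alignment.fasta"))
    write_partitions(ev$scheme, file.path(dir, "partitions.txt"))
    write_tree_file(truth$species, file.path(dir, "species_tree.nwk"))
    write_tree_file(truth$gene_trees$plastid, file.path(dir, "gene_tree_plastid.nwk"))
    write_tree_file(truth$gene_trees$nuclear, file.path(dir, "gene_tree_nuclear.nwk"))
    utils::write.table(truth$hybrids, file.path(dir, "truth_hybrids.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$model <- sprintf("%s+G%d", cfg$model$name, cfg$model$n_cat)
    writeLines(paste0(names(unlist(cfg[c("n_taxa", "lambda", "height",
                                         "n_hybrids", "donor_min_dist",
                                         "share_its", "share_plastid",
                                         "missing_frac", "seed")])), " = ",
                      unlist(cfg[c("n_taxa", "lambda", "height", "n_hybrids",
                                   "donor_min_dist", "share_its",
                                   "share_plastid", "missing_frac", "seed")])),
               file.path(dir, "config.txt"))
  }
  invisible(bundle)
}
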