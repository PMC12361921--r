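# Independent oracles and fixture builders used across the suite.

# exhaustive-enumeration log-likelihood: sums over all internal-node state
# assignments (independent of the pruning implementation)
brute_force_loglik <- function(aln, tree, model) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  E <- nrow(tr$edge)
  IU <- phylodup:::IUPAC_PARTIALS
  L <- aln$n_columns
  total <- 0
  states <- as.matrix(expand.grid(rep(list(1:4), nint)))
  site_L <- numeric(L)
  for (k in seq_len(model$n_cat)) {
    P_list <- lapply(seq_len(E), function(e)
      transition_matrix(model, tr$edge.length[e], model$cat_rates[k]))
    Lk <- numeric(L)
    for (a in seq_len(nrow(states))) {
      s <- states[a, ]
      pr <- rep(model$freqs[s[1L]], L)     # root = first internal node
      for (e in seq_len(E)) {
        u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
        su <- s[u - ntip]
        if (v <= ntip) {
          chars <- aln$mat[tr$tip.label[v], ]
          pr <- pr * colSums(P_list[[e]][su, ] * IU[, chars])
        } else {
          pr <- pr * P_list[[e]][su, s[v - ntip]]
        }
      }
      Lk <- Lk + pr
    }
    site_L <- site_L + model$cat_weights[k] * Lk
  }
  sum(log(site_L))
}

# simulate an alignment on a tree with the package generator machinery
sim_on_tree <- function(tree, model, L, seed = NULL) {
  phylodup:::with_seed_(seed, {
    mat <- phylodup:::evolve_states(tree, model, L)
    alignment(mat)
  })
}

# random alignment with ambiguity and missing characters
random_alignment <- function(ntaxa, L, labels = paste0("t", seq_len(ntaxa))) {
  mat <- matrix(sample(c("A", "C", "G", "T", "R", "-", "?"),
                       ntaxa * L, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.04, 0.04, 0.04)),
                ntaxa, L, dimnames = list(labels, NULL))
  alignment(mat)
}

# random model from the implemented family
random_model <- function(family = c("JC", "HKY", "GTR"), gamma = NA) {
  name <- sample(family, 1L)
  if (is.na(gamma)) gamma <- runif(1) < 0.5
  freqs <- if (name == "JC") rep(0.25, 4) else { x <- runif(4, 0.5, 1.5); x / sum(x) }
  substitution_model(name, freqs = freqs, kappa = runif(1, 1, 4),
                     rates = c(runif(5, 0.3, 3), 1),
                     gamma_shape = if (gamma) runif(1, 0.3, 2) else NULL)
}

# random binary tree with uniform branch lengths
random_tree <- function(n, lmin = 0.01, lmax = 1) {
  tr <- ape::rtree(n, br = function(k) runif(k, lmin, lmax))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# split sets (bitmask keys over sorted labels) of a tree, via ape machinery
# (independent of phylodup::tree_splits)
ape_split_masks <- function(tree) {
  labs <- sort(tree$tip.label)
  ntip <- length(labs)
  pp <- ape::prop.part(tree)   # rooted-representation clades; the mask
                               # canonicalization below collapses root sides
  masks <- integer(0)
  for (cl in pp) {
    tipset <- attr(pp, "labels")[cl]
    if (length(tipset) < 2L || length(tipset) > ntip - 2L) next
    bits <- sum(2^(match(tipset, labs) - 1L))
    full <- 2^ntip - 1L
    if (bitwAnd(bits, 1L) == 1L) bits <- bitwAnd(bitwNot(bits), full)
    masks <- c(masks, bits)
  }
  sort(unique(masks))
}

# default per-region model list for a benchmark config
bench_models <- function(cfg, scheme) {
  stats::setNames(rep(list(cfg$model), length(region_names(scheme))),
                  region_names(scheme))
}
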