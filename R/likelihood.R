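# Likelihood engine: pattern compression, workspaces, pruning log-likelihood
# and edge environments (partials on both sides of an edge) used for fast
# 1-D branch-length optimization.

# compress alignment columns into unique site patterns
compress_patterns <- function(mat) {
  pat <- apply(mat, 2L, paste0, collapse = "")
  u <- unique(pat)
  idx <- match(pat, u)
  w <- tabulate(idx, length(u))
  chars <- matrix(unlist(strsplit(u, "")), nrow = nrow(mat))
  ntaxa <- nrow(mat)
  tipp <- array(0, dim = c(4L, length(u), ntaxa))
  for (tx in seq_len(ntaxa))
    tipp[, , tx] <- IUPAC_PARTIALS[, chars[tx, ], drop = FALSE]
  list(tipp = tipp, patw = as.numeric(w), n_columns = ncol(mat))
}

#' Build a likelihood dataset over one or more partition regions
#'
#' Precomputes site patterns and tip partial indicators for each region so
#' repeated likelihood evaluations are cheap.  Each region carries its own
#' substitution model and relative rate multiplier (partitioned likelihood:
#' the total log-likelihood is the sum over regions, each region scaling
#' the shared branch lengths by its rate).
#'
#' @param aln a \code{dup_alignment}.
#' @param scheme a \code{dup_partitions}, or NULL to treat the whole
#'   alignment as a single region.
#' @param regions character vector of region names to include (default: all
#'   in the scheme, or the single pseudo-region \code{"all"}).
#' @param klass shorthand: include all regions of this class.
#' @param models a single \code{dup_model} (recycled) or a named list of
#'   models, one per region.
#' @param rates numeric vector of per-region rate multipliers (default 1).
#' @return an object of class \code{"dup_likdata"}.
#' @export
lik_data <- function(aln, scheme = NULL, regions = NULL, klass = NULL,
                     models, rates = NULL) {
  if (is.null(regions)) {
    regions <- if (is.null(scheme)) "all" else class_regions(scheme, klass)
  }
  if (inherits(models, "dup_model")) {
    models <- stats::setNames(rep(list(models), length(regions)), regions)
  }
  if (is.null(rates)) rates <- stats::setNames(rep(1, length(regions)), regions)
  if (is.null(names(rates))) names(rates) <- regions
  rgs <- lapply(regions, function(nm) {
    cols <- if (is.null(scheme)) seq_len(aln$n_columns) else region_columns(scheme, nm)
    cp <- compress_patterns(aln$mat[, cols, drop = FALSE])
    c(list(name = nm, model = models[[nm]], rate = unname(rates[nm])), cp)
  })
  names(rgs) <- regions
  structure(list(taxa = aln$taxa, regions = rgs), class = "dup_likdata")
}

# workspace: lik_data with tip partials permuted into a tree's tip order
lik_workspace <- function(ld, tip_labels) {
  idx <- match(tip_labels, ld$taxa)
  if (anyNA(idx))
    stop("tree leaf without sequence data: ",
         paste(tip_labels[is.na(idx)], collapse = ", "))
  rgs <- lapply(ld$regions, function(rg) {
    rg$tipp <- rg$tipp[, , idx, drop = FALSE]
    rg
  })
  structure(list(regions = rgs, tips = tip_labels), class = "dup_ws")
}

# canonical engine form: unrooted, postorder edge ordering
eng_tree <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  tr <- if (ape::is.rooted(tree) && length(tree$tip.label) > 3L)
    ape::unroot(tree) else tree
  ape::reorder.phylo(tr, "postorder")
}

# kernel call for one region; want = postorder edge rows needing
# environments; arrays = also return the per-edge child contributions and
# per-node parent-side partials (local NNI rescoring)
region_prune <- function(rg, tr, want = integer(0), arrays = FALSE) {
  e <- rg$model$eig
  prune_env(tr$edge, length(tr$tip.label), tr$edge.length * rg$rate,
            rg$tipp, e$U, e$values, e$Uinv, rg$model$cat_rates,
            rg$model$cat_weights, rg$model$freqs, rg$patw,
            as.integer(want), arrays)
}

ws_loglik <- function(ws, tr) {
  sum(vapply(ws$regions, function(rg) region_prune(rg, tr)$loglik, 0))
}

ws_envs <- function(ws, tr, want) {
  lapply(ws$regions, function(rg) region_prune(rg, tr, want))
}

# log-likelihood as a function of one edge's length, from precomputed envs;
# `slot` indexes into the `want` vector used to build the envs
env_objective <- function(ws, envs, slot) {
  rgs <- ws$regions
  function(t) {
    tot <- 0
    for (r in seq_along(rgs)) {
      rg <- rgs[[r]]; en <- envs[[r]]
      e <- rg$model$eig
      tot <- tot + env_loglik(en$ux, en$uxs, en$dn, en$dns, slot,
                              length(rg$patw), rg$model$n_cat, t * rg$rate,
                              e$U, e$values, e$Uinv, rg$model$cat_rates,
                              rg$model$cat_weights, rg$patw)
    }
    tot
  }
}

# log-likelihood and its first two derivatives in one edge's length
env_dobjective <- function(ws, envs, slot) {
  rgs <- ws$regions
  function(t) {
    out <- c(0, 0, 0)
    for (r in seq_along(rgs)) {
      rg <- rgs[[r]]; en <- envs[[r]]
      e <- rg$model$eig
      v <- env_dloglik(en$ux, en$uxs, en$dn, en$dns, slot,
                       length(rg$patw), rg$model$n_cat, t * rg$rate,
                       e$U, e$values, e$Uinv, rg$model$cat_rates,
                       rg$model$cat_weights, rg$patw)
      out <- out + c(v[1L], v[2L] * rg$rate, v[3L] * rg$rate^2)
    }
    out
  }
}

# guarded-Newton 1-D maximization of one branch length on [0, BL_MAX];
# g returns c(loglik, d1, d2); never returns a value below g(t0)
optimize_edge <- function(g, t0, lower = 0, upper = 10, tol = 1e-6,
                          max_iter = 25L) {
  t <- min(max(t0, lower), upper)
  v <- g(t)
  best_t <- t; best_ll <- v[1L]
  for (it in seq_len(max_iter)) {
    if (!is.finite(v[2L]) || abs(v[2L]) < 1e-10) break
    step <- if (is.finite(v[3L]) && v[3L] < 0) -v[2L] / v[3L]
            else sign(v[2L]) * 0.5 * (abs(t) + 0.05)
    tn <- min(max(t + step, lower), upper)
    vn <- g(tn)
    tries <- 0L
    while ((!is.finite(vn[1L]) || vn[1L] < best_ll - 1e-12) && tries < 8L) {
      tn <- (tn + t) / 2
      vn <- g(tn)
      tries <- tries + 1L
    }
    if (is.finite(vn[1L]) && vn[1L] > best_ll) { best_ll <- vn[1L]; best_t <- tn }
    if (abs(tn - t) < tol) { break }
    t <- tn; v <- vn
  }
  if (best_t > lower && best_t < lower + 1e-4) {
    v0 <- g(lower)
    if (v0[1L] >= best_ll) { best_t <- lower; best_ll <- v0[1L] }
  }
  list(t = best_t, ll = best_ll)
}

#' Felsenstein pruning log-likelihood of an alignment on a tree
#'
#' The likelihood is computed by the pruning algorithm with per-node
#' rescaling (no silent underflow) and averaging over discrete-gamma rate
#' categories.  The value is invariant to the traversal root of the
#' unrooted tree.  Ambiguity codes contribute an indicator over their
#' compatible states; \code{-}, \code{?} and \code{N} are uninformative.
#'
#' @param aln a \code{dup_alignment} containing all tree leaves.
#' @param tree a \code{phylo} with branch lengths.
#' @param model a \code{dup_model}.
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(aln, tree, model) {
  tr <- eng_tree(tree)
  ld <- lik_data(subset_alignment(aln, taxa = intersect(aln$taxa, tr$tip.label)),
                 models = model)
  ws <- lik_workspace(ld, tr$tip.label)
  ws_loglik(ws, tr)
}

#' Partitioned log-likelihood (sum over regions)
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param ld a \code{dup_likdata} whose taxa include the tree leaves.
#' @return total log-likelihood, with per-region values as attribute
#'   \code{"by_region"}.
#' @export
partitioned_loglik <- function(tree, ld) {
  tr <- eng_tree(tree)
  ws <- lik_workspace(ld, tr$tip.label)
  per <- vapply(ws$regions, function(rg) region_prune(rg, tr)$loglik, 0)
  structure(sum(per), by_region = per)
}
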