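# Branch-length optimization, NNI hill-climbing, and branch supports.

BL_MAX <- 10   # branch-length upper bound (expected substitutions/site)

as_likdata <- function(data, model = NULL, scheme = NULL, klass = NULL) {
  if (inherits(data, "dup_likdata")) return(data)
  if (inherits(data, "dup_alignment")) {
    if (is.null(model)) stop("a substitution model is required")
    return(lik_data(data, scheme = scheme, klass = klass, models = model))
  }
  stop("data must be a dup_alignment or dup_likdata")
}

#' Optimize branch lengths by cyclic 1-D maximization
#'
#' Each branch is optimized by bracketed 1-D search on [0, 10] given the
#' partials on both sides of the edge; sweeps repeat until the total
#' log-likelihood improves by less than \code{tol}.  The returned tree
#' carries the final log-likelihood in attribute \code{"loglik"}, which is
#' never smaller than the starting value.
#'
#' @param tree a \code{phylo} with starting branch lengths.
#' @param data a \code{dup_likdata}, or a \code{dup_alignment} with
#'   \code{model}.
#' @param model substitution model (when \code{data} is an alignment).
#' @param tol log-likelihood convergence tolerance.
#' @param max_sweeps maximum number of sweeps over all edges.
#' @return the tree with optimized \code{edge.length}.
#' @export
optimize_branch_lengths <- function(tree, data, model = NULL, tol = 1e-6,
                                    max_sweeps = 20L) {
  ld <- as_likdata(data, model)
  tr <- eng_tree(tree)
  ws <- lik_workspace(ld, tr$tip.label)
  res <- optimize_bl_ws(tr, ws, tol, max_sweeps)
  res
}

# region descriptors handed to the C++ sweep
ws_gs_regions <- function(ws) {
  lapply(ws$regions, function(rg) {
    e <- rg$model$eig
    list(tipp = rg$tipp, patw = rg$patw, U = e$U, ev = e$values,
         Uinv = e$Uinv, rates = rg$model$cat_rates,
         catw = rg$model$cat_weights, freqs = rg$model$freqs,
         rate = rg$rate)
  })
}

# workspace-level implementation (reused by search and placement).  Each
# C++ Gauss-Seidel sweep optimizes every edge in place with fresh
# traversal-order partials; sweeps repeat until the exact log-likelihood
# improves by less than tol, and the best-seen lengths are kept (the
# final value never drops below the starting one).
optimize_bl_ws <- function(tr, ws, tol = 1e-6, max_sweeps = 25L) {
  regions <- ws_gs_regions(ws)
  best_ll <- ws_loglik(ws, tr)
  best_tr <- tr
  for (sweep in seq_len(max_sweeps)) {
    tr$edge.length <- as.numeric(
      gs_sweep(tr$edge, length(tr$tip.label), tr$edge.length, regions,
               BL_MAX))
    new_ll <- ws_loglik(ws, tr)
    if (new_ll > best_ll) {
      improved <- new_ll - best_ll
      best_tr <- tr; best_ll <- new_ll
    } else {
      tr <- best_tr
      improved <- 0
    }
    if (improved < tol) break
  }
  attr(best_tr, "loglik") <- best_ll
  best_tr
}

# rows of the edge matrix whose child is an internal node
internal_edge_rows <- function(tr) {
  which(tr$edge[, 2L] > length(tr$tip.label))
}

# one NNI alternative across internal edge row e (alt = 1 or 2): swaps the
# subtree next to the parent with one of the two subtrees under the child.
# Returns the rearranged tree (postorder) and the rows of the 5 affected
# edges, or NULL if the edge is not internal.
nni_move <- function(tr, e, alt) {
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
  if (v <= ntip) return(NULL)
  urows <- which(tr$edge[, 1L] == u)
  a_row <- setdiff(urows, e)[1L]          # subtree beside the parent
  vrows <- which(tr$edge[, 1L] == v)
  c_row <- vrows[alt]
  if (is.na(a_row) || is.na(c_row)) return(NULL)
  edge <- tr$edge
  edge[a_row, 1L] <- v
  edge[c_row, 1L] <- u
  cand <- tr
  cand$edge <- edge
  attr(cand, "order") <- NULL
  cand <- ape::reorder.phylo(cand, "postorder")
  touched <- which(cand$edge[, 1L] %in% c(u, v) | cand$edge[, 2L] %in% c(u, v))
  list(tree = cand, rows = touched, nodes = c(u, v))
}

# Local (quartet) scoring of the three NNI resolutions of every internal
# edge.  One full pruning pass per region caches, for each edge, the
# child-side contribution z (subtree partial with the edge's own P matrix
# applied) and, for each internal node, the parent-side partial; the
# likelihood of any resolution around an edge is then a product of four
# cached factors joined by the central edge, whose length alone is
# re-optimized (the fast aBayes/NNI scoring scheme).  Per-pattern scaling
# constants are identical across the three resolutions of an edge, so the
# returned differences are exact for the cached branch lengths.
local_nni_deltas <- function(ws, tr) {
  ntip <- length(tr$tip.label)
  nR <- length(ws$regions)
  arrs <- lapply(ws$regions, function(rg) {
    a <- region_prune(rg, tr, arrays = TRUE)
    P <- length(rg$patw); K <- rg$model$n_cat
    z <- a$z; dim(z) <- c(4L, P, K, nrow(tr$edge))
    up <- a$up; dim(up) <- c(4L, P, K, tr$Nnode)
    list(z = z, up = up, ll = a$loglik)
  })
  ll0 <- sum(vapply(arrs, `[[`, 0, "ll"))
  pair_obj <- function(lefts, rights) {
    function(t) {
      out <- c(0, 0, 0)
      for (r in seq_len(nR)) {
        rg <- ws$regions[[r]]
        e <- rg$model$eig
        P <- length(rg$patw)
        zero <- numeric(P)
        v <- env_dloglik(lefts[[r]], zero, rights[[r]], zero, 1L, P,
                         rg$model$n_cat, t * rg$rate, e$U, e$values,
                         e$Uinv, rg$model$cat_rates, rg$model$cat_weights,
                         rg$patw)
        out <- out + c(v[1L], v[2L] * rg$rate, v[3L] * rg$rate^2)
      }
      out
    }
  }
  rows <- internal_edge_rows(tr)
  res <- data.frame(row = rows, node = tr$edge[rows, 2L],
                    d1 = NA_real_, d2 = NA_real_)
  root <- ntip + 1L
  for (ri in seq_along(rows)) {
    e <- rows[ri]
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    arows <- setdiff(which(tr$edge[, 1L] == u), e)
    vrows <- which(tr$edge[, 1L] == v)
    facs <- lapply(seq_len(nR), function(r) {
      z <- arrs[[r]]$z
      f1 <- z[, , , arows[1L]]
      f2 <- if (u == root) {
        if (length(arows) > 1L)
          z[, , , arows[2L]] * ws$regions[[r]]$model$freqs
        else array(ws$regions[[r]]$model$freqs,
                   dim = dim(z)[1:3])
      } else arrs[[r]]$up[, , , u - ntip]
      list(f1 = f1, f2 = f2, f3 = z[, , , vrows[1L]],
           f4 = z[, , , vrows[2L]])
    })
    score <- function(lf, rf) {
      lefts <- lapply(facs, function(f) f[[lf[1L]]] * f[[lf[2L]]])
      rights <- lapply(facs, function(f) f[[rf[1L]]] * f[[rf[2L]]])
      optimize_edge(pair_obj(lefts, rights), tr$edge.length[e],
                    upper = BL_MAX)$ll
    }
    cur <- score(c("f1", "f2"), c("f3", "f4"))
    res$d1[ri] <- score(c("f3", "f2"), c("f1", "f4")) - cur
    res$d2[ri] <- score(c("f4", "f2"), c("f3", "f1")) - cur
  }
  attr(res, "loglik") <- ll0
  res
}

#' NNI hill-climbing tree search
#'
#' Starting from a binary tree, repeatedly evaluates both
#' nearest-neighbor-interchange alternatives of every internal edge (with
#' branch-length re-optimization on the affected edges), accepts the best
#' improving move, re-optimizes all branch lengths, and stops when no move
#' improves the log-likelihood by more than \code{tol}.  Deterministic
#' given the input tree and data.
#'
#' @inheritParams optimize_branch_lengths
#' @param max_iter maximum number of accepted moves.
#' @return tree with attribute \code{"loglik"}; log-likelihood never
#'   decreases relative to the (branch-length-optimized) start.
#' @export
nni_search <- function(tree, data, model = NULL, tol = 1e-6, max_iter = 50L) {
  ld <- as_likdata(data, model)
  tr <- eng_tree(tree)
  ws <- lik_workspace(ld, tr$tip.label)
  tr <- optimize_bl_ws(tr, ws)
  ll <- attr(tr, "loglik")
  for (iter in seq_len(max_iter)) {
    sc <- local_nni_deltas(ws, tr)
    deltas <- c(sc$d1, sc$d2)
    if (max(deltas) <= tol) break
    k <- which.max(deltas)                     # best improving move
    e <- sc$row[(k - 1L) %% nrow(sc) + 1L]
    alt <- if (k > nrow(sc)) 2L else 1L
    mv <- nni_move(tr, e, alt)
    cand <- optimize_bl_ws(mv$tree, ws)
    if (attr(cand, "loglik") <= ll + tol) break  # screen overestimated
    tr <- cand
    ll <- attr(tr, "loglik")
  }
  attr(tr, "loglik") <- ll
  tr
}

#' aBayes posterior of the best NNI resolution
#'
#' Softmax under a uniform prior over the three resolutions of an internal
#' edge: \code{max_i L_i / sum_i L_i}, computed stably from
#' log-likelihoods; equals 1/3 when all three are equal and is always in
#' [1/3, 1].
#'
#' @param lls numeric vector of (up to three) log-likelihoods.
#' @return the posterior probability of the best resolution.
#' @export
abayes_posterior <- function(lls) {
  m <- max(lls)
  1 / sum(exp(lls - m))
}

#' aBayes branch supports
#'
#' For each internal edge, the log-likelihoods of the three NNI resolutions
#' (current tree plus both alternatives, each scored from cached subtree
#' partials with the central branch re-optimized — the fast aBayes scoring
#' scheme) are combined under a uniform prior:
#' support = max_i L_i / sum_i L_i, which lies in [1/3, 1].  The input tree
#' should carry optimized branch lengths.
#'
#' @inheritParams optimize_branch_lengths
#' @return tree annotated with aBayes values in its node labels (bootstrap
#'   values, if present, are preserved).
#' @export
abayes_supports <- function(tree, data, model = NULL) {
  ld <- as_likdata(data, model)
  tr <- eng_tree(tree)
  ws <- lik_workspace(ld, tr$tip.label)
  ntip <- length(tr$tip.label)
  sup <- get_supports(tr)
  ab <- rep(NA_real_, tr$Nnode)
  sc <- local_nni_deltas(ws, tr)
  for (ri in seq_len(nrow(sc)))
    ab[sc$node[ri] - ntip] <- abayes_posterior(c(0, sc$d1[ri], sc$d2[ri]))
  tr2 <- set_supports(tr, bs = sup$bs, ab = ab)
  attr(tr2, "loglik") <- attr(sc, "loglik")
  tr2
}

#' Nonparametric bootstrap branch supports
#'
#' Columns are resampled with replacement within each region (region sizes
#' preserved), each replicate is re-inferred, and every internal edge of
#' the reference tree is annotated with the percentage of replicate trees
#' displaying its split.  By default replicates are re-inferred by neighbor
#' joining on JC distances; \code{refine = TRUE} adds the NNI likelihood
#' search to each replicate.
#'
#' @param aln a \code{dup_alignment}.
#' @param scheme partition scheme (NULL: one region spanning the alignment).
#' @param tree reference \code{phylo} to annotate.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed (reproducible resampling).
#' @param klass,regions region selection, as in \code{\link{lik_data}}.
#' @param refine logical: refine each replicate tree by NNI search.
#' @param models per-region models (only used when \code{refine = TRUE}).
#' @param d_max distance cap for saturated/undefined pairs.
#' @return tree annotated with bootstrap percentages (aBayes values, if
#'   present, are preserved).
#' @export
bootstrap_supports <- function(aln, scheme = NULL, tree, B = 200L,
                               seed = NULL, klass = NULL, regions = NULL,
                               refine = FALSE, models = NULL, d_max = 5) {
  stopifnot(B >= 1L)
  if (is.null(regions))
    regions <- if (is.null(scheme)) "all" else class_regions(scheme, klass)
  taxa <- tree$tip.label
  cols_by_region <- lapply(regions, function(nm)
    if (is.null(scheme)) seq_len(aln$n_columns) else region_columns(scheme, nm))
  cols <- unlist(cols_by_region)
  offs <- c(0L, cumsum(lengths(cols_by_region)))
  mat <- aln$mat[taxa, cols, drop = FALSE]
  n <- length(taxa)
  L <- ncol(mat)
  defined <- matrix(mat %in% STATE_ORDER, n, L)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  M <- matrix(0, np, L); Df <- matrix(0, np, L)
  for (p in seq_len(np)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    d <- defined[i, ] & defined[j, ]
    Df[p, ] <- d
    M[p, ] <- d & (mat[i, ] != mat[j, ])
  }
  ref_splits <- tree_splits(tree)
  keys <- vapply(ref_splits, function(s) split_key(s$side, taxa), "")
  hits <- stats::setNames(numeric(length(keys)), keys)
  with_seed_(seed, {
    for (b in seq_len(B)) {
      take_all <- unlist(lapply(seq_along(cols_by_region), function(r) {
        idx <- (offs[r] + 1L):offs[r + 1L]
        sample(idx, length(idx), replace = TRUE)
      }))
      w <- tabulate(take_all, nbins = L)
      ndef <- as.vector(Df %*% w)
      pmis <- ifelse(ndef > 0, as.vector(M %*% w) / pmax(ndef, 1), NA)
      dv <- ifelse(is.na(pmis) | pmis >= 0.75, d_max,
                   pmin(pmax(-0.75 * log(pmax(1 - 4 * pmis / 3, 1e-12)), 0),
                        d_max))
      D <- matrix(0, n, n, dimnames = list(taxa, taxa))
      D[t(pairs)] <- dv; D[t(pairs[2:1, , drop = FALSE])] <- dv
      rep_tree <- neighbor_joining(D)
      if (refine) {
        rep_aln <- alignment(mat[, take_all, drop = FALSE])
        mdl <- if (!is.null(models)) models[[1L]] else
          substitution_model("HKY", freqs = empirical_freqs(rep_aln),
                             gamma_shape = 1)
        rep_tree <- nni_search(rep_tree, rep_aln, mdl)
      }
      rk <- vapply(tree_splits(rep_tree), function(s) split_key(s$side, taxa), "")
      hits[keys %in% rk] <- hits[keys %in% rk] + 1
    }
  })
  sup <- get_supports(tree)
  bs <- rep(NA_real_, tree$Nnode)
  ntip <- length(tree$tip.label)
  for (si in seq_along(ref_splits))
    bs[ref_splits[[si]]$node - ntip] <- 100 * hits[keys[si]] / B
  set_supports(tree, bs = bs, ab = sup$ab)
}
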