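# Model selection (AIC) and the composed partitioned inference pipeline.

# parse "GTR+G"-style candidate labels
parse_candidate <- function(label) {
  parts <- strsplit(label, "+", fixed = TRUE)[[1L]]
  list(name = parts[1L], gamma = length(parts) > 1L && parts[2L] == "G")
}

#' Candidate model labels
#' @param gamma_only keep only +G candidates.
#' @export
model_candidates <- function(gamma_only = FALSE) {
  base <- c("JC", "K80", "HKY", "GTR")
  if (gamma_only) paste0(base, "+G") else c(base, paste0(base, "+G"))
}

# fit one candidate on a fixed topology: alternate model-parameter
# optimization (Nelder-Mead on log scale) with branch-length sweeps
fit_candidate <- function(aln, tree, name, gamma, rounds = 2L) {
  freqs <- if (name %in% c("HKY", "GTR")) empirical_freqs(aln) else rep(0.25, 4)
  make <- function(par) {
    i <- 0L
    kappa <- 2; rates <- rep(1, 6); alpha <- if (gamma) 1 else NULL
    if (name %in% c("K80", "HKY")) { kappa <- exp(par[i + 1L]); i <- i + 1L }
    if (name == "GTR") { rates <- c(exp(par[i + seq_len(5)]), 1); i <- i + 5L }
    if (gamma) alpha <- exp(par[i + 1L])
    substitution_model(name, freqs = freqs, kappa = kappa, rates = rates,
                       gamma_shape = alpha)
  }
  npar <- (name %in% c("K80", "HKY")) + 5L * (name == "GTR") + gamma
  par <- rep(0, npar)
  ld <- lik_data(aln, models = make(par))
  tr <- eng_tree(tree)
  ws <- lik_workspace(ld, tr$tip.label)
  converged <- TRUE
  ll <- -Inf
  for (r in seq_len(rounds)) {
    if (npar > 0L) {
      obj <- function(p) {
        m <- try(make(p), silent = TRUE)
        if (inherits(m, "try-error")) return(1e10)
        ws$regions[[1L]]$model <- m
        -ws_loglik(ws, tr)
      }
      opt <- if (npar == 1L)
        stats::optim(par, obj, method = "Brent", lower = -10, upper = 10,
                     control = list(reltol = 1e-8))
      else
        stats::optim(par, obj, method = "Nelder-Mead",
                     control = list(maxit = 200L * npar, reltol = 1e-8))
      if (opt$convergence != 0L) converged <- FALSE
      par <- opt$par
    }
    ld$regions[[1L]]$model <- make(par)
    ws$regions[[1L]]$model <- make(par)
    tr <- optimize_bl_ws(tr, ws, max_sweeps = 5L)
    ll <- attr(tr, "loglik")
  }
  model <- make(par)
  list(model = model, log_likelihood = ll, k = model$k,
       aic = aic(ll, model$k), converged = converged, tree = tr)
}

#' AIC-based substitution model selection on a fixed topology
#'
#' Each candidate in the JC/K80/HKY/GTR x {+G} family is fitted by
#' maximum likelihood (model parameters and branch lengths; the topology is
#' fixed, so branch lengths are a shared parameter set and are excluded
#' from the AIC parameter count).  Free-parameter counts: JC 0; K80 1
#' (kappa); HKY 4 (kappa + 3 empirical frequencies); GTR 8 (5
#' exchangeabilities + 3 frequencies); +G adds 1 (alpha).  Ties are broken
#' toward fewer parameters.
#'
#' @param aln a \code{dup_alignment}.
#' @param tree fixed topology with starting branch lengths (e.g. an NJ
#'   tree); if NULL, an NJ tree from JC distances is used.
#' @param candidates character vector of candidate labels, e.g.
#'   \code{c("JC", "GTR+G")}.
#' @return list of class \code{"dup_modelfit"}: the winning \code{model},
#'   \code{log_likelihood}, \code{k}, \code{aic}, \code{converged} and a
#'   comparison \code{table} over all candidates.  Non-convergence of an
#'   optimizer is flagged in the table, never silent.
#' @export
select_model <- function(aln, tree = NULL, candidates = model_candidates()) {
  if (is.null(tree))
    tree <- neighbor_joining(distance_matrix(aln))
  fits <- lapply(candidates, function(cc) {
    p <- parse_candidate(cc)
    fit_candidate(aln, tree, p$name, p$gamma)
  })
  tab <- data.frame(candidate = candidates,
                    lnL = vapply(fits, `[[`, 0, "log_likelihood"),
                    k = vapply(fits, function(f) f$k, 0L),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    converged = vapply(fits, `[[`, TRUE, "converged"))
  # minimize AIC; near-ties (within 1e-8) go to the smaller k
  ord <- order(round(tab$aic, 8), tab$k)
  win <- fits[[ord[1L]]]
  structure(list(model = win$model, log_likelihood = win$log_likelihood,
                 k = win$k, aic = win$aic, converged = win$converged,
                 candidate = candidates[ord[1L]], table = tab),
            class = "dup_modelfit")
}

#' @export
print.dup_modelfit <- function(x, ...) {
  cat(sprintf("Selected model: %s (lnL = %.4f, k = %d, AIC = %.4f)\n",
              x$candidate, x$log_likelihood, x$k, x$aic))
  print(x$table)
  invisible(x)
}

# optimize per-region rate multipliers (renormalized to weighted mean 1;
# the global scale is pushed into the branch lengths)
optimize_region_rates <- function(tr, ld, rounds = 2L) {
  if (length(ld$regions) < 2L) return(list(tree = tr, ld = ld))
  ws <- lik_workspace(ld, tr$tip.label)
  ncols <- vapply(ld$regions, `[[`, 0, "n_columns")
  for (r in seq_len(rounds)) {
    for (i in seq_along(ld$regions)) {
      rg <- ws$regions[[i]]
      f <- function(m) { rg$rate <- m; region_prune(rg, tr)$loglik }
      opt <- stats::optimize(f, c(0.02, 50), maximum = TRUE, tol = 1e-4)
      if (opt$objective > f(ws$regions[[i]]$rate)) {
        ws$regions[[i]]$rate <- opt$maximum
        ld$regions[[i]]$rate <- opt$maximum
      }
    }
    rates <- vapply(ld$regions, `[[`, 0, "rate")
    mean_rate <- sum(rates * ncols) / sum(ncols)
    for (i in seq_along(ld$regions)) {
      ld$regions[[i]]$rate <- rates[i] / mean_rate
      ws$regions[[i]]$rate <- rates[i] / mean_rate
    }
    tr$edge.length <- tr$edge.length * mean_rate
  }
  list(tree = tr, ld = ld)
}

#' Full partitioned tree inference
#'
#' Pipeline composition: per-region AIC model selection (unless models are
#' supplied), NJ starting tree from JC distances, partitioned branch-length
#' and per-region rate optimization, NNI search, and branch supports.
#' Reproducible given \code{seed}.
#'
#' @param aln a \code{dup_alignment}.
#' @param scheme a \code{dup_partitions} (NULL: single region).
#' @param klass restrict to one partition class (\code{"plastid"} /
#'   \code{"nuclear"}).
#' @param regions explicit region names (overrides \code{klass}).
#' @param models named list of per-region \code{dup_model}s; NULL triggers
#'   selection.
#' @param rates fixed per-region rate multipliers (NULL: optimized).
#' @param candidates candidate labels for model selection.
#' @param supports which supports to annotate: \code{"abayes"},
#'   \code{"bootstrap"}, \code{"both"} or \code{"none"}.
#' @param start optional starting tree for the NNI search (default: NJ on
#'   JC distances).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param refine_bootstrap refine bootstrap replicates by NNI search.
#' @return a \code{phylo} with attributes \code{"loglik"}, \code{"models"},
#'   \code{"rates"} and (optionally) support-annotated node labels.
#' @export
infer_tree <- function(aln, scheme = NULL, klass = NULL, regions = NULL,
                       models = NULL, rates = NULL,
                       candidates = model_candidates(gamma_only = TRUE),
                       supports = c("abayes", "bootstrap", "both", "none"),
                       B = 200L, seed = NULL, refine_bootstrap = FALSE,
                       start = NULL) {
  supports <- match.arg(supports)
  if (is.null(regions))
    regions <- if (is.null(scheme)) "all" else class_regions(scheme, klass)
  cols <- if (is.null(scheme)) seq_len(aln$n_columns) else
    sort(unlist(lapply(regions, region_columns, scheme = scheme)))
  sub <- alignment(aln$mat[, cols, drop = FALSE])
  no_data <- names(which(defined_fraction(sub) == 0))
  if (length(no_data))
    stop("taxa without data in the selected regions: ",
         paste(no_data, collapse = ", "))
  if (length(sub$taxa) < 4L) stop("need at least 4 taxa")
  if (is.null(start)) {
    D <- distance_matrix(sub, impute = TRUE)
    start <- neighbor_joining(D)
  } else stopifnot(setequal(start$tip.label, sub$taxa))
  if (is.null(models)) {
    models <- lapply(regions, function(nm) {
      raln <- alignment(aln$mat[, if (is.null(scheme)) cols else
        region_columns(scheme, nm), drop = FALSE])
      select_model(raln, start, candidates)$model
    })
    names(models) <- regions
  }
  ld <- lik_data(aln, scheme = scheme, regions = regions, models = models,
                 rates = rates)
  fixed_rates <- !is.null(rates)
  tr <- optimize_branch_lengths(start, ld)
  if (!fixed_rates) {
    rr <- optimize_region_rates(tr, ld)
    tr <- rr$tree; ld <- rr$ld
  }
  tr <- nni_search(tr, ld)
  if (!fixed_rates) {
    rr <- optimize_region_rates(tr, ld)
    tr <- optimize_branch_lengths(rr$tree, rr$ld)
    ld <- rr$ld
  }
  if (supports %in% c("abayes", "both"))
    tr <- abayes_supports(tr, ld)
  if (supports %in% c("bootstrap", "both"))
    tr <- bootstrap_supports(aln, scheme, tr, B = B, seed = seed,
                             regions = regions, models = models)
  attr(tr, "models") <- models
  attr(tr, "rates") <- vapply(ld$regions, `[[`, 0, "rate")
  tr
}
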