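# Time-reversible nucleotide substitution models.  The rate matrix Q is
# built from six exchangeabilities s (order AC, AG, AT, CG, CT, GT) and
# stationary frequencies pi as Q[i,j] = s[ij] * pi[j], and is rescaled so
# the expected number of substitutions per site per unit branch length is 1.

STATE_ORDER <- c("A", "C", "G", "T")

# indicator partials for IUPAC codes over (A, C, G, T); '-'/'?'/'N' = missing
iupac_table <- function() {
  tab <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"),
    N = STATE_ORDER, "-" = STATE_ORDER, "?" = STATE_ORDER)
  m <- sapply(tab, function(st) as.numeric(STATE_ORDER %in% st))
  rownames(m) <- STATE_ORDER
  m
}
IUPAC_PARTIALS <- iupac_table()

#' Construct a substitution model
#'
#' Supported families: \code{JC}, \code{K80}, \code{HKY}, \code{GTR},
#' optionally with discrete-gamma rate heterogeneity (equal-probability
#' categories, category means).
#'
#' @param name one of \code{"JC"}, \code{"K80"}, \code{"HKY"}, \code{"GTR"}.
#' @param freqs stationary base frequencies (A, C, G, T); must sum to 1.
#'   Forced equal for JC/K80.
#' @param kappa transition/transversion rate ratio (K80, HKY).
#' @param rates six GTR exchangeabilities (AC, AG, AT, CG, CT, GT); the GT
#'   rate acts as reference.  Ignored for simpler models.
#' @param gamma_shape gamma shape alpha (> 0), or \code{NULL} for
#'   rate-homogeneous sites.
#' @param n_cat number of discrete gamma categories (default 4 when
#'   \code{gamma_shape} is given).
#' @return object of class \code{"dup_model"}: Q matrix, its eigen system,
#'   category rates and free-parameter count.
#' @export
substitution_model <- function(name = c("JC", "K80", "HKY", "GTR"),
                               freqs = rep(0.25, 4), kappa = 2,
                               rates = rep(1, 6), gamma_shape = NULL,
                               n_cat = if (is.null(gamma_shape)) 1L else 4L) {
  name <- match.arg(name)
  if (name %in% c("JC", "K80")) freqs <- rep(0.25, 4)
  if (abs(sum(freqs) - 1) > 1e-8) stop("base frequencies must sum to 1")
  freqs <- freqs / sum(freqs)
  ex <- switch(name,
    JC  = rep(1, 6),
    K80 = c(1, kappa, 1, 1, kappa, 1),
    HKY = c(1, kappa, 1, 1, kappa, 1),
    GTR = rates)
  if (any(ex < 0)) stop("exchangeabilities must be non-negative")
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma shape must be positive")
  Q <- build_q(ex, freqs)
  k <- switch(name, JC = 0L, K80 = 1L, HKY = 1L + 3L, GTR = 5L + 3L)
  if (!is.null(gamma_shape)) k <- k + 1L
  cat_rates <- discrete_gamma(if (is.null(gamma_shape)) Inf else gamma_shape,
                              n_cat)
  structure(list(name = name, exchangeabilities = ex, freqs = freqs,
                 kappa = if (name %in% c("K80", "HKY")) kappa else NA_real_,
                 gamma_shape = gamma_shape, n_cat = as.integer(n_cat),
                 cat_rates = cat_rates, cat_weights = rep(1 / n_cat, n_cat),
                 Q = Q, eig = eigen_q(Q, freqs), k = k),
            class = "dup_model")
}

#' @export
print.dup_model <- function(x, ...) {
  cat(sprintf("%s%s model, %d free parameter(s)\n", x$name,
              if (!is.null(x$gamma_shape)) sprintf("+G%d (alpha=%.4g)",
                                                   x$n_cat, x$gamma_shape) else "",
              x$k))
  invisible(x)
}

# rate matrix, scaled to 1 expected substitution/site/unit length
build_q <- function(ex, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(STATE_ORDER, STATE_ORDER))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(6)) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    Q[i, j] <- ex[p] * freqs[j]
    Q[j, i] <- ex[p] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q / scale
}

# eigen system of a reversible Q via its symmetrization
eigen_q <- function(Q, freqs) {
  sq <- sqrt(freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sq) %*% e$vectors      # Q = U diag(values) Uinv
  Uinv <- t(e$vectors) %*% diag(sq)
  list(values = e$values, U = U, Uinv = Uinv)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model a \code{dup_model}.
#' @param t branch length (expected substitutions/site), >= 0.
#' @param rate rate-category multiplier (> 0).
#' @return 4x4 row-stochastic matrix over (A, C, G, T).
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  if (rate <= 0) stop("rate multiplier must be positive")
  e <- model$eig
  P <- e$U %*% (exp(e$values * t * rate) * e$Uinv)
  dimnames(P) <- list(STATE_ORDER, STATE_ORDER)
  # clip tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma rate multipliers (mean of equal-probability categories)
#'
#' Mean rate of each of K equal-probability categories of a Gamma(alpha,
#' alpha) distribution (mean 1).  \code{alpha = Inf} gives the homogeneous
#' limit (all multipliers 1).
#'
#' @param alpha gamma shape (> 0, or Inf).
#' @param K number of categories (>= 1).
#' @return numeric vector of K multipliers with mean 1.
#' @export
discrete_gamma <- function(alpha, K) {
  if (K < 1L) stop("K must be >= 1")
  if (is.infinite(alpha)) return(rep(1, K))
  if (alpha <= 0) stop("gamma shape must be positive")
  if (K == 1L) return(1)
  q <- stats::qgamma(seq_len(K - 1L) / K, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  m <- K * diff(p)
  m / mean(m)  # renormalize away discretization round-off
}

#' AIC of a fitted model
#' @param log_likelihood maximized log-likelihood.
#' @param k number of free parameters.
#' @export
aic <- function(log_likelihood, k) 2 * k - 2 * log_likelihood

# empirical base frequencies of an alignment (defined IUPAC bases only,
# ambiguity codes counted fractionally)
empirical_freqs <- function(aln) {
  informative <- setdiff(colnames(IUPAC_PARTIALS), c("N", "-", "?"))
  tab <- table(factor(as.vector(aln$mat), levels = informative))
  weights <- sweep(IUPAC_PARTIALS[, informative, drop = FALSE], 2,
                   colSums(IUPAC_PARTIALS[, informative, drop = FALSE]), "/")
  counts <- as.vector(weights %*% as.numeric(tab))
  if (sum(counts) == 0) return(rep(0.25, 4))
  counts / sum(counts)
}
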