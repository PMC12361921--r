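# Pairwise ML distances and neighbor joining (starting trees).

#' Maximum-likelihood pairwise distance
#'
#' Under JC the closed form \eqn{d = -3/4 \log(1 - 4p/3)} is used, where
#' \eqn{p} is the mismatch proportion over columns where both sequences
#' carry an unambiguous base.  Under other models the distance is the 1-D
#' maximizer of the pairwise likelihood.  Saturated pairs return the cap
#' \code{d_max}; pairs with no shared defined column return \code{NA}
#' (a missing-distance signal, never 0).
#'
#' @param seq_a,seq_b character vectors (single characters) or strings.
#' @param model a \code{dup_model} (default JC).
#' @param d_max saturation cap (default 5).
#' @return non-negative distance, or NA if no shared defined columns.
#' @export
ml_distance <- function(seq_a, seq_b, model = substitution_model("JC"),
                        d_max = 5) {
  if (length(seq_a) == 1L) seq_a <- strsplit(toupper(seq_a), "")[[1L]]
  if (length(seq_b) == 1L) seq_b <- strsplit(toupper(seq_b), "")[[1L]]
  stopifnot(length(seq_a) == length(seq_b))
  ok <- seq_a %in% STATE_ORDER & seq_b %in% STATE_ORDER
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  if (model$name == "JC" && model$n_cat == 1L) {
    p <- sum(seq_a[ok] != seq_b[ok]) / n
    if (p >= 0.75) return(d_max)
    return(min(max(-0.75 * log(1 - 4 * p / 3), 0), d_max))
  }
  counts <- table(factor(seq_a[ok], STATE_ORDER), factor(seq_b[ok], STATE_ORDER))
  nll <- function(t) {
    L <- 0
    for (k in seq_len(model$n_cat)) {
      P <- transition_matrix(model, t, model$cat_rates[k])
      L <- L + model$cat_weights[k] * (model$freqs * P)
    }
    -sum(counts * log(pmax(L, 1e-300)))
  }
  opt <- stats::optimize(nll, c(0, d_max), tol = 1e-8)
  if (nll(0) <= opt$objective) return(0)
  min(opt$minimum, d_max)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln a \code{dup_alignment}.
#' @param model a \code{dup_model}.
#' @param d_max saturation cap.
#' @param impute fill pairs with no shared defined columns (e.g. two
#'   single-class duplicated entries of different classes) with the
#'   smallest one-intermediate path distance \code{min_k d(a,k) + d(k,b)}
#'   (then \code{d_max} if still undefined), so NJ can run; the final tree
#'   is refined by likelihood anyway.
#' @return symmetric matrix with zero diagonal; NA marks pairs with no
#'   shared defined columns (unless imputed).
#' @export
distance_matrix <- function(aln, model = substitution_model("JC"), d_max = 5,
                            impute = FALSE) {
  n <- length(aln$taxa)
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- ml_distance(aln$mat[i, ], aln$mat[j, ], model,
                                        d_max)
  if (impute && anyNA(D)) {
    miss <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    for (r in seq_len(nrow(miss))) {
      i <- miss[r, 1L]; j <- miss[r, 2L]
      via <- which(!is.na(D[i, ]) & !is.na(D[j, ]))
      via <- setdiff(via, c(i, j))
      d <- if (length(via)) min(D[i, via] + D[via, j]) else d_max
      D[i, j] <- D[j, i] <- min(d, d_max)
    }
  }
  D
}

#' Neighbor joining
#'
#' Standard NJ agglomeration (Saitou & Nei).  Ties in the Q criterion are
#' broken toward the lowest-index pair.  Negative estimated branch lengths
#' are clamped to zero (the clamped deficit is recorded in attribute
#' \code{"clamped"}).
#'
#' @param D symmetric distance matrix with zero diagonal, >= 3 taxa, no
#'   missing entries, labelled rows/columns.
#' @return an unrooted \code{phylo}.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (anyNA(D)) stop("distance matrix has missing entries")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ids <- seq_len(n)                      # phylo node id of each active row
  next_id <- n + 2L                      # n+1 reserved for the final root
  edges <- NULL                          # rows: (node_a, node_b, length)
  clamped <- 0
  Dm <- unname(D)
  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(Dm)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * Dm[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { clamped <- clamped - li; li <- 0 }
    if (lj < 0) { clamped <- clamped - lj; lj <- 0 }
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    edges <- rbind(edges, c(next_id, ids[i], li), c(next_id, ids[j], lj))
    Dm <- Dm[-c(i, j), -c(i, j), drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    ids <- c(ids[-c(i, j)], next_id)
    next_id <- next_id + 1L
  }
  # final 3-way join at the root (node n+1)
  root <- n + 1L
  if (length(ids) == 3L) {
    la <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
    lb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
    lc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
    ls <- c(la, lb, lc)
    clamped <- clamped + sum(-pmin(ls, 0))
    ls <- pmax(ls, 0)
    edges <- rbind(edges, cbind(root, ids, ls))
  } else {                               # exactly 3 taxa at entry
    stop("internal error")               # unreachable: loop guards m > 3
  }
  tree <- assemble_unrooted(edges, labels, root, n)
  attr(tree, "clamped") <- clamped
  tree
}

# build a phylo from an undirected edge list by rooting at `root`
assemble_unrooted <- function(edges, labels, root, ntip) {
  adj <- list()
  key <- function(a) as.character(a)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]; l <- edges[r, 3L]
    adj[[key(a)]] <- rbind(adj[[key(a)]], c(b, l))
    adj[[key(b)]] <- rbind(adj[[key(b)]], c(a, l))
  }
  # preorder from root; renumber internal nodes ntip+1, ntip+2, ...
  renum <- integer(0)
  renum[key(root)] <- ntip + 1L
  nxt <- ntip + 2L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  stack <- list(c(root, NA))
  while (length(stack)) {
    cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- cur[1L]; from <- cur[2L]
    for (r in seq_len(nrow(adj[[key(node)]]))) {
      nb <- adj[[key(node)]][r, 1L]; l <- adj[[key(node)]][r, 2L]
      if (!is.na(from) && nb == from) next
      if (nb > ntip) {                  # internal neighbor: renumber
        renum[key(nb)] <- nxt; nxt <- nxt + 1L
        childid <- renum[key(nb)]
      } else childid <- nb
      parent <- c(parent, renum[key(node)])
      child <- c(child, childid)
      elen <- c(elen, l)
      if (nb > ntip) stack[[length(stack) + 1L]] <- c(nb, node)
    }
  }
  nint <- nxt - ntip - 1L
  tree <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                         edge.length = elen, tip.label = labels,
                         Nnode = nint), class = "phylo")
  ape::reorder.phylo(tree, "postorder")
}
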