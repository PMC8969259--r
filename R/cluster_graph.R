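#' Initialize the complete weighted cluster graph
#'
#' Every sequence starts as a singleton vertex with vertex weight
#' `w_ii = 1`; off-diagonal entries of `W` are the pairwise similarities.
#' The graph keeps the primitive (initial) similarity matrix so that all
#' vertex and edge weights after contraction are exact arithmetic means of
#' primitive-pair similarities, and a ledger of forbidden vertex pairs
#' which carry the sentinel weight `-|V|^2` in `W`.
#'
#' @param W0 symmetric similarity matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @param ids optional primitive sequence ids (defaults to rownames).
#' @return An object of class `afc_graph` with fields `W` (current
#'   vertex/edge weights), `rho` (primitive counts per vertex), `members`
#'   (primitive indices per vertex), `forbidden` (2-column index matrix),
#'   `W0` and `ids`.
#' @export
init_graph <- function(W0, ids = rownames(W0)) {
  W0 <- as.matrix(W0)
  n <- nrow(W0)
  if (n != ncol(W0) || max(abs(W0 - t(W0))) > 1e-9)
    stop("similarity matrix must be symmetric")
  if (max(abs(diag(W0) - 1)) > 1e-9)
    stop("similarity matrix must have unit diagonal")
  if (min(W0) < -1e-9 || max(W0) > 1 + 1e-9)
    stop("similarities must lie in [0, 1]")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(W = W0, rho = rep(1L, n),
                 members = as.list(seq_len(n)),
                 forbidden = matrix(integer(0), ncol = 2),
                 W0 = W0, ids = ids),
            class = "afc_graph")
}

#' @export
print.afc_graph <- function(x, ...) {
  cat(sprintf("afc_graph: %d vertices over %d primitive sequences, %d forbidden pair(s)\n",
              nrow(x$W), sum(x$rho), nrow(x$forbidden)))
  invisible(x)
}

n_vertices <- function(graph) nrow(graph$W)

# Mean similarity over all unordered primitive pairs inside one set.
primitive_intra_mean <- function(W0, prim) {
  m <- length(prim)
  if (m == 1) return(1)
  (sum(W0[prim, prim]) - m) / (m * (m - 1))
}

#' Contract the graph by a set of clusters
#'
#' Replaces each cluster by one vertex. The new vertex weight is the mean
#' similarity over all primitive pairs inside the cluster, and each new
#' edge weight is the mean over all primitive pairs across the two
#' clusters (so a weight at any contraction depth is always the exact
#' primitive-pair average). Clusters listed together in a sibling group
#' (bins split from one raw cluster) become forbidden pairs: their edges
#' get the sentinel weight `-|V'|^2` so no subsequent raw cluster can
#' reunite them. Forbidden status is hereditary across contractions.
#'
#' @param graph an `afc_graph`.
#' @param clusters list of integer vectors partitioning the current
#'   vertex set.
#' @param sibling_groups list of integer vectors; each vector indexes
#'   entries of `clusters` that originate from the same raw cluster.
#' @return The contracted `afc_graph`.
#' @export
contract_graph <- function(graph, clusters, sibling_groups = list()) {
  stopifnot(inherits(graph, "afc_graph"))
  n <- n_vertices(graph)
  flat <- unlist(clusters)
  if (length(flat) != n || !setequal(flat, seq_len(n)) || anyDuplicated(flat))
    stop("clusters must partition the vertex set")
  m <- length(clusters)
  members <- lapply(clusters, function(cl)
    sort(unlist(graph$members[cl], use.names = FALSE)))
  rho <- lengths(members)

  # block sums of the primitive similarity matrix give every new weight as
  # an exact primitive-pair mean in one pass
  np <- sum(rho)
  grp <- integer(np)
  for (i in seq_len(m)) grp[members[[i]]] <- i
  S <- rowsum(t(rowsum(graph$W0, grp)), grp)
  S <- (S + t(S)) / 2  # summation order differs across the diagonal
  W <- S / outer(rho, rho)
  diag(W) <- ifelse(rho == 1, 1, (diag(S) - rho) / (rho^2 - rho))
  dimnames(W) <- NULL

  # map old vertex -> new vertex, propagate the forbidden ledger
  map <- integer(n)
  for (i in seq_len(m)) map[clusters[[i]]] <- i
  forb <- graph$forbidden
  if (nrow(forb) > 0) {
    a <- map[forb[, 1]]
    b <- map[forb[, 2]]
    if (any(a == b))
      stop("internal error: a forbidden pair was merged")
    forb <- cbind(pmin(a, b), pmax(a, b))
  }
  for (grp in sibling_groups) {
    if (length(grp) < 2) next
    prs <- t(utils::combn(sort(as.integer(grp)), 2))
    forb <- rbind(forb, prs)
  }
  forb <- unique(forb)
  if (nrow(forb) > 0)
    W[rbind(forb, forb[, 2:1, drop = FALSE])] <- -(m^2)

  structure(list(W = W, rho = rho, members = members, forbidden = forb,
                 W0 = graph$W0, ids = graph$ids),
            class = "afc_graph")
}
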