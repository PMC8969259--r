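#' Constant Potts Model quality of a partition
#'
#' `q = sum over unordered intra-cluster vertex pairs of (w_ij - gamma)`.
#' The graph is complete, so every intra-cluster pair contributes; the
#' diagonal vertex weights are not edges and contribute nothing. The
#' all-singleton partition scores 0, which is the CPM baseline.
#'
#' @param graph an `afc_graph`.
#' @param sigma integer vector of cluster labels, one per vertex.
#' @param gamma resolution parameter in `[0, 1]`.
#' @return The quality score `q`.
#' @export
cpm_quality <- function(graph, sigma, gamma) {
  stopifnot(inherits(graph, "afc_graph"))
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  n <- n_vertices(graph)
  if (length(sigma) != n) stop("sigma must label every vertex")
  q <- 0
  for (lab in unique(sigma)) {
    idx <- which(sigma == lab)
    m <- length(idx)
    if (m < 2) next
    sub <- graph$W[idx, idx]
    q <- q + sum(sub[upper.tri(sub)]) - gamma * m * (m - 1) / 2
  }
  q
}

# Single-vertex local moves until no move (to another cluster or to a new
# singleton) increases q. Deterministic sweep order. Runs in O(n^2) per
# sweep on the complete graph.
polish_partition <- function(W, sigma, gamma) {
  n <- length(sigma)
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      own <- sigma[v]
      wv <- W[v, ]
      sums <- rowsum(wv, sigma)       # per-cluster sum incl. v's own entry
      labs <- as.integer(rownames(sums))
      sizes <- tabulate(sigma, nbins = max(sigma))[labs]
      # contribution of v to cluster c if v were a member of c; v's own
      # diagonal entry is a vertex weight, not an edge, so remove it
      gain <- sums[, 1] - gamma * sizes
      k_own <- match(own, labs)
      gain[k_own] <- sums[k_own, 1] - wv[v] - gamma * (sizes[k_own] - 1)
      best <- max(gain, 0)  # 0 = move to a new singleton cluster
      if (best > gain[k_own] + 1e-12) {
        if (best > 0) {
          sigma[v] <- labs[which(gain == best)[1]]
        } else {
          sigma[v] <- max(sigma) + 1L
        }
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  match(sigma, unique(sigma))
}

#' Detect raw clusters by CPM maximization
#'
#' Runs the Leiden algorithm (igraph) with the Constant Potts Model at
#' resolution `gamma` on the current graph, from several seeded starts,
#' then applies deterministic single-vertex local moves until no move
#' increases `q`. The returned partition has `q >= 0`, is locally
#' optimal, never co-clusters a forbidden pair (their sentinel edge
#' weight makes any such partition strictly worse than splitting), and is
#' identical across calls with the same seed.
#'
#' @param graph an `afc_graph`.
#' @param gamma resolution in `[0, 1]`.
#' @param seed integer seed for the Leiden starts.
#' @param n_starts number of independent Leiden starts (best `q` kept).
#' @return Integer vector of raw-cluster labels (1-based, first-occurrence
#'   order).
#' @export
detect_raw_clusters <- function(graph, gamma, seed = 0, n_starts = 3) {
  stopifnot(inherits(graph, "afc_graph"))
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  n <- n_vertices(graph)
  if (n == 1) return(1L)

  W <- graph$W
  Wz <- W
  diag(Wz) <- 0  # vertex weights are not self-loops
  g <- igraph::graph_from_adjacency_matrix(Wz, mode = "undirected",
                                           weighted = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  best_sigma <- seq_len(n)  # all singletons, q = 0
  best_q <- 0
  for (r in seq_len(n_starts)) {
    set.seed(seed + (r - 1L))
    cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                                 resolution = gamma, n_iterations = 10)
    sigma <- polish_partition(W, as.integer(igraph::membership(cl)), gamma)
    q <- cpm_quality(graph, sigma, gamma)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_sigma <- sigma
    }
  }
  sigma <- polish_partition(W, best_sigma, gamma)

  # post-conditions: no forbidden pair co-clustered, and every vertex in a
  # non-singleton raw cluster has mean intra-cluster edge weight > gamma
  if (nrow(graph$forbidden) > 0 &&
      any(sigma[graph$forbidden[, 1]] == sigma[graph$forbidden[, 2]]))
    stop("internal error: forbidden pair co-clustered")
  for (lab in unique(sigma)) {
    idx <- which(sigma == lab)
    if (length(idx) < 2) next
    for (v in idx) {
      mw <- mean(W[v, setdiff(idx, v)])
      if (mw < gamma - 1e-9)
        stop("internal error: intra-cluster mean weight below gamma")
    }
  }
  match(sigma, unique(sigma))
}

# Turn a label vector into a list of vertex index sets.
partition_to_clusters <- function(sigma) {
  lapply(unique(sigma), function(lab) which(sigma == lab))
}
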