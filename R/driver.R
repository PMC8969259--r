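#' Core clustering parameters
#'
#' The resolution schedule starts at `gamma_high` (default 0.95, which
#' should stay close to the maximum edge weight 1 so the first raw
#' clusters are robust against the size bias of low-resolution CPM) and
#' decreases by `delta` (default 0.025; larger steps re-introduce size
#' bias) until it passes the soft cut-off `gamma_low` (default 0.75,
#' suggested range 0.7-0.8).
#'
#' @param gamma_high starting resolution.
#' @param gamma_low soft cut-off referenced by the binning score.
#' @param delta resolution step size.
#' @param precluster_limit sequence count above which greedy
#'   pre-clustering partitions the input before graph clustering.
#' @param seed RNG seed for raw-cluster detection.
#' @return An object of class `afc_core_params`.
#' @export
core_params <- function(gamma_high = 0.95, gamma_low = 0.75, delta = 0.025,
                        precluster_limit = 20000, seed = 0) {
  if (!(gamma_low > 0 && gamma_low < gamma_high && gamma_high <= 1))
    stop("need 0 < gamma_low < gamma_high <= 1")
  if (delta <= 0) stop("delta must be positive")
  structure(list(gamma_high = gamma_high, gamma_low = gamma_low,
                 delta = delta, precluster_limit = as.integer(precluster_limit),
                 seed = as.integer(seed)),
            class = "afc_core_params")
}

# Resolution schedule gamma_high, gamma_high - delta, ... while
# gamma > gamma_low - delta, on an exact decimal grid (scaled integers)
# so binary floating point cannot corrupt the loop bound.
gamma_schedule <- function(core) {
  scale <- 1e6
  gh <- round(core$gamma_high * scale)
  gl <- round(core$gamma_low * scale)
  dl <- round(core$delta * scale)
  gs <- seq(gh, gl - dl + 1, by = -dl)
  gs[gs > gl - dl] / scale
}

new_result <- function(clusters, centers, alphabet, params) {
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) min(x), character(1)))
  structure(list(clusters = clusters[ord], centers = centers[ord],
                 alphabet = alphabet, params = params),
            class = "afc_result")
}

#' @export
print.afc_result <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("afc_result: %d sequence(s) in %d cluster(s) (%d singleton(s), largest %d)\n",
              sum(sz), length(sz), sum(sz == 1), max(sz)))
  invisible(x)
}

# Run the iterative graph clustering on one sequence partition (>= 2
# sequences, all of length >= k). Returns clusters of ids plus centers.
cluster_partition <- function(seqs, sketch, core) {
  W0 <- build_similarity_matrix(seqs, sketch)
  graph <- init_graph(W0, ids = seqs$id)
  gammas <- gamma_schedule(core)
  for (it in seq_along(gammas)) {
    gamma <- gammas[it]
    sigma <- detect_raw_clusters(graph, gamma, seed = core$seed)
    raw <- partition_to_clusters(sigma)
    if (it == 1) {
      L <- raw
      siblings <- list()
    } else {
      L <- list()
      siblings <- list()
      for (rc in raw) {
        if (length(rc) == 1) {
          L[[length(L) + 1]] <- rc
        } else {
          bins <- bin_raw_cluster(rc, graph, core$gamma_low)
          at <- length(L)
          L <- c(L, bins)
          if (length(bins) > 1)
            siblings[[length(siblings) + 1]] <- at + seq_along(bins)
        }
      }
    }
    graph <- contract_graph(graph, L, siblings)
  }
  clusters <- lapply(graph$members, function(ix) sort(seqs$id[ix]))
  centers <- vapply(graph$members, function(ix) {
    if (length(ix) == 1) return(seqs$id[ix])
    select_center(seqs$id[ix], W0[ix, ix, drop = FALSE], seqs)
  }, character(1))
  list(clusters = clusters, centers = centers)
}

#' Cluster sequences with adaptive similarity cut-offs
#'
#' The main algorithm. Pairwise Mash similarities define a complete
#' weighted graph in which every sequence starts as a singleton vertex.
#' At each resolution of the schedule (see [core_params()]) CPM-scored
#' Leiden community detection proposes raw clusters; in the first
#' iteration the raw clusters are accepted directly, afterwards each raw
#' cluster is split into validated bins by the adaptive cut-off rule
#' ([bin_raw_cluster()]); the graph is then contracted so every validated
#' cluster becomes one vertex, with bins split from the same raw cluster
#' forbidden from re-merging. The clusters of the final iteration are
#' returned, expanded to sequence ids.
#'
#' Sequences shorter than the k-mer size are excluded with a warning.
#' When the input exceeds `precluster_limit` sequences (or `precluster`
#' is set) the input is first divided by greedy sketch-based
#' pre-clustering at similarity threshold `gamma_low` and each partition
#' is clustered independently.
#'
#' @param seqs an [afc_seqs] object.
#' @param sketch an [sketch_params()] object.
#' @param core a [core_params()] object.
#' @param precluster force the pre-clustering step regardless of input
#'   size.
#' @return An object of class `afc_result`: `clusters` (list of id sets,
#'   ordered by descending size then smallest member id) and `centers`
#'   (one representative id per cluster).
#' @export
af_cluster <- function(seqs, sketch = sketch_params(), core = core_params(),
                       precluster = FALSE) {
  stopifnot(inherits(seqs, "afc_seqs"))
  p <- resolve_sketch_params(sketch, seqs$alphabet)
  short <- nchar(seqs$residues) < p$k
  if (any(short)) {
    warning("excluding ", sum(short), " sequence(s) shorter than k = ", p$k,
            ": ", paste(seqs$id[short], collapse = ", "))
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) stop("no sequences remain after length filtering")
  if (length(seqs) == 1)
    return(new_result(list(seqs$id), seqs$id, seqs$alphabet,
                      list(sketch = p, core = core)))

  if (precluster || length(seqs) > core$precluster_limit) {
    parts <- precluster_partitions(seqs, sketch, core$gamma_low)
  } else {
    parts <- list(seq_len(length(seqs)))
  }

  clusters <- list()
  centers <- character(0)
  for (part in parts) {
    sub <- seqs[part]
    if (length(sub) == 1) {
      clusters[[length(clusters) + 1]] <- sub$id
      centers <- c(centers, sub$id)
    } else {
      res <- cluster_partition(sub, sketch, core)
      clusters <- c(clusters, res$clusters)
      centers <- c(centers, res$centers)
    }
  }
  new_result(clusters, centers, seqs$alphabet,
             list(sketch = p, core = core))
}

#' Greedy sketch-based pre-clustering
#'
#' Divides the input into partitions whose cross-partition similarity is
#' below `gamma_low`: each sequence, in input order, joins the first
#' partition whose representative (its first sequence) has Mash
#' similarity `>= gamma_low`, otherwise it opens a new partition. A
#' final single-linkage pass unions partitions whose representatives meet
#' the threshold.
#'
#' @param seqs an [afc_seqs] object.
#' @param sketch an [sketch_params()] object.
#' @param gamma_low the similarity threshold.
#' @return List of integer index vectors, one per partition, in order of
#'   partition creation.
#' @export
precluster_partitions <- function(seqs, sketch = sketch_params(),
                                  gamma_low = 0.75) {
  stopifnot(inherits(seqs, "afc_seqs"))
  sketches <- lapply(seq_len(length(seqs)), function(i)
    build_sketch(seqs$residues[i], sketch, alphabet = seqs$alphabet))
  reps <- integer(0)
  assign_to <- integer(length(seqs))
  for (i in seq_len(length(seqs))) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      sim <- 1 - mash_distance(sketches[[i]], sketches[[reps[r]]])
      if (sim >= gamma_low) {
        assign_to[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign_to[i] <- length(reps)
    }
  }
  # single-linkage union of partitions whose representatives meet the
  # threshold (usually a no-op: each representative scored below the
  # threshold against all earlier ones when it was created)
  np <- length(reps)
  parent <- seq_len(np)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (np > 1) {
    for (a in seq_len(np - 1)) {
      for (b in seq(a + 1, np)) {
        sim <- 1 - mash_distance(sketches[[reps[a]]], sketches[[reps[b]]])
        if (sim >= gamma_low) parent[find(b)] <- find(a)
      }
    }
  }
  root <- vapply(seq_len(np), find, integer(1))
  groups <- unique(root)
  lapply(groups, function(g) which(assign_to %in% which(root == g)))
}
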