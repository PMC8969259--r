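#' Order the vertices of a raw cluster for binning
#'
#' Sorts the intra-cluster edges by descending weight (ties: smaller
#' vertex index pair first) and appends, for each edge in that order, any
#' endpoint not yet listed. When both endpoints are absent the one
#' representing the larger underlying cluster (larger `rho`) is appended
#' first; equal `rho` falls back to the smaller index.
#'
#' @param raw_cluster integer vector of vertex indices, length >= 2.
#' @param graph an `afc_graph`.
#' @return Integer vector: the vertex list `J`.
#' @export
order_vertices <- function(raw_cluster, graph) {
  stopifnot(inherits(graph, "afc_graph"), length(raw_cluster) >= 2)
  v <- sort(as.integer(raw_cluster))
  prs <- t(utils::combn(v, 2))
  w <- graph$W[prs]
  ord <- order(-w, prs[, 1], prs[, 2])
  J <- integer(0)
  for (e in ord) {
    i <- prs[e, 1]; j <- prs[e, 2]
    in_i <- i %in% J; in_j <- j %in% J
    if (!in_i && !in_j) {
      first <- if (graph$rho[j] > graph$rho[i]) c(j, i) else c(i, j)
      J <- c(J, first)
    } else if (!in_i) {
      J <- c(J, i)
    } else if (!in_j) {
      J <- c(J, j)
    }
    if (length(J) == length(v)) break
  }
  J
}

#' Average intra-bin weight
#'
#' For a singleton bin this is the vertex weight `w_ii`; otherwise the
#' rho-weighted mean combining within-vertex primitive pairs (weight
#' `rho(rho-1)/2` on `w_ii`) and cross-vertex primitive pairs (weight
#' `rho_i * rho_j` on `w_ij`), i.e. the mean similarity over all
#' primitive pairs inside the bin.
#'
#' @param B integer vector of vertex indices (non-empty).
#' @param graph an `afc_graph`.
#' @return The intra-bin weight `I_bin`.
#' @export
intra_bin_weight <- function(B, graph) {
  stopifnot(length(B) >= 1)
  if (length(B) == 1) return(graph$W[B, B])
  rho <- graph$rho[B]
  wd <- diag(graph$W)[B]
  num <- sum(rho * (rho - 1) / 2 * wd)
  den <- sum(rho * (rho - 1) / 2)
  prs <- t(utils::combn(seq_along(B), 2))
  rr <- rho[prs[, 1]] * rho[prs[, 2]]
  num <- num + sum(rr * graph$W[cbind(B[prs[, 1]], B[prs[, 2]])])
  den <- den + sum(rr)
  num / den
}

#' Average weight between a candidate vertex and a bin
#'
#' The rho-weighted mean of the edge weights between `v_t` and the bin
#' members: `I = sum(rho_i * w_it) / sum(rho_i)`.
#'
#' @param B integer vector of bin member indices.
#' @param v_t candidate vertex index, not in `B`.
#' @param graph an `afc_graph`.
#' @return The attachment weight `I`.
#' @export
attach_weight <- function(B, v_t, graph) {
  stopifnot(!(v_t %in% B))
  rho <- graph$rho[B]
  sum(rho * graph$W[B, v_t]) / sum(rho)
}

#' Bin admission score
#'
#' `Q = 2 I - I_bin - gamma_low`. `Q > 0` is exactly the adaptive cut-off
#' rule: the cluster separation `I_bin - I` must be strictly smaller than
#' the cut-off `I - gamma_low` for `v_t` to be admissible to the bin.
#'
#' @inheritParams attach_weight
#' @param gamma_low the soft cut-off.
#' @return The score `Q`.
#' @export
bin_score <- function(B, v_t, graph, gamma_low) {
  2 * attach_weight(B, v_t, graph) - intra_bin_weight(B, graph) - gamma_low
}

#' Split a raw cluster into validated bins
#'
#' The first vertex of the ordered list `J` seeds the first bin. Each
#' subsequent vertex is scored against every existing bin and joins the
#' bin with the highest strictly positive score; when no score is
#' positive it seeds a new bin. Ties on the maximal score go to the
#' earliest-created bin.
#'
#' @param raw_cluster integer vector of vertex indices, length >= 2.
#' @param graph an `afc_graph`.
#' @param gamma_low the soft cut-off.
#' @return List of integer vectors (bins) in creation order.
#' @export
bin_raw_cluster <- function(raw_cluster, graph, gamma_low) {
  J <- order_vertices(raw_cluster, graph)
  bins <- list(J[1])
  for (v_t in J[-1]) {
    scores <- vapply(bins, function(B) bin_score(B, v_t, graph, gamma_low),
                     numeric(1))
    best <- max(scores)
    if (best > 0) {
      k <- which(scores == best)[1]
      bins[[k]] <- c(bins[[k]], v_t)
    } else {
      bins[[length(bins) + 1]] <- v_t
    }
  }
  bins
}
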