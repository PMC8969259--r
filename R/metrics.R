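check_partitions <- function(clusters, classes) {
  a <- unlist(clusters)
  b <- unlist(classes)
  if (anyDuplicated(a) || anyDuplicated(b) || !setequal(a, b))
    stop("clusters and classes must partition the same id set")
  length(a)
}

#' Normalized mutual information between clusters and classes
#'
#' `NMI = 2 I(L; Omega) / (H(L) + H(Omega))` with mutual information and
#' entropies computed from the overlap counts (natural logarithm; the
#' value is log-base invariant). When both partitions are a single group
#' the value is defined as 1.
#'
#' @param clusters list of id vectors (the clustering `L`).
#' @param classes list of id vectors (the ground-truth classes `Omega`).
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(clusters, classes) {
  N <- check_partitions(clusters, classes)
  H <- function(parts) {
    p <- lengths(parts) / N
    -sum(p * log(p))
  }
  hl <- H(clusters)
  ho <- H(classes)
  if (hl + ho == 0) return(1)
  mi <- 0
  for (C in clusters) {
    for (w in classes) {
      nk <- length(intersect(C, w))
      if (nk == 0) next
      mi <- mi + nk / N * log(N * nk / (length(C) * length(w)))
    }
  }
  2 * mi / (hl + ho)
}

#' Purity of a clustering against known classes
#'
#' `Purity = (1/N) sum over clusters of the largest overlap with any
#' class`.
#'
#' @inheritParams nmi
#' @return Purity in `(0, 1]`.
#' @export
purity <- function(clusters, classes) {
  N <- check_partitions(clusters, classes)
  sum(vapply(clusters, function(C)
    max(vapply(classes, function(w) length(intersect(C, w)), numeric(1))),
    numeric(1))) / N
}

#' Mean silhouette coefficient of a clustering
#'
#' For each element, `(d_neighbor - d_intra) / max(d_neighbor, d_intra)`
#' where `d_intra` is its mean distance to the other members of its
#' cluster and `d_neighbor` the smallest mean distance to another
#' cluster; members of singleton clusters contribute 0. Distances should
#' be true sequence distances (1 - alignment identity) when used to judge
#' sequence clusters.
#'
#' @param distances symmetric distance matrix with zero diagonal; ids as
#'   dimnames when `clusters` holds ids.
#' @param clusters list of at least two id (or index) vectors
#'   partitioning the matrix rows.
#' @return The mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(distances, clusters) {
  distances <- as.matrix(distances)
  if (length(clusters) < 2)
    stop("silhouette requires at least 2 clusters")
  if (is.character(clusters[[1]])) {
    ids <- rownames(distances)
    clusters <- lapply(clusters, function(cl) match(cl, ids))
    if (anyNA(unlist(clusters))) stop("cluster ids absent from matrix")
  }
  n <- sum(lengths(clusters))
  total <- 0
  for (ci in seq_along(clusters)) {
    own <- clusters[[ci]]
    for (s in own) {
      if (length(own) == 1) next  # singleton contributes 0
      a <- mean(distances[s, setdiff(own, s)])
      b <- min(vapply(clusters[-ci], function(cl)
        mean(distances[s, cl]), numeric(1)))
      m <- max(a, b)
      if (m > 0) total <- total + (b - a) / m
    }
  }
  total / n
}
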