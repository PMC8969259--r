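# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formula
# transcription, and set arithmetic on k-mer strings.

# uniform integer draw that stays safe when lo == hi
pick_int <- function(lo, hi) {
  v <- seq(lo, hi)
  v[sample.int(length(v), 1)]
}

# random symmetric similarity matrix with unit diagonal
random_sim_matrix <- function(n, lo = 0, hi = 1) {
  W <- matrix(runif(n * n, lo, hi), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

# the worked five-vertex graph: w12 = 0.89 and a four-vertex clique
# {v1, v3, v4, v5} with the remaining pairs at weight 0
toy_graph5 <- function() {
  W <- diag(5)
  W[1, 2] <- 0.89
  W[1, 3] <- 0.84; W[1, 4] <- 0.86; W[1, 5] <- 0.87
  W[3, 4] <- 0.85; W[3, 5] <- 0.87; W[4, 5] <- 0.86
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  init_graph(W)
}

# CPM quality computed directly from the definition, independent of the
# package implementation
oracle_q <- function(W, sigma, gamma) {
  n <- length(sigma)
  q <- 0
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      if (sigma[i] == sigma[j]) q <- q + W[i, j] - gamma
  q
}

# all set partitions of n elements as label vectors (restricted growth
# strings, iterative successor algorithm)
enum_partitions <- function(n) {
  out <- list()
  a <- rep(1L, n)
  repeat {
    out[[length(out) + 1]] <- a
    # successor: find rightmost position that can be incremented
    j <- n
    while (j > 1) {
      if (a[j] <= max(a[1:(j - 1)])) break
      j <- j - 1
    }
    if (j == 1) break
    a[j] <- a[j] + 1L
    if (j < n) a[(j + 1):n] <- 1L
  }
  out
}

# global CPM optimum by brute force
brute_cpm_opt <- function(W, gamma) {
  best <- -Inf
  for (sigma in enum_partitions(nrow(W))) {
    q <- oracle_q(W, sigma, gamma)
    if (q > best) best <- q
  }
  best
}

# TRUE when no single-vertex move (to another cluster or a new singleton)
# increases q by more than tol
is_locally_optimal <- function(W, sigma, gamma, tol = 1e-9) {
  n <- length(sigma)
  for (v in seq_len(n)) {
    own <- which(sigma == sigma[v] & seq_len(n) != v)
    cur <- if (length(own) == 0) 0 else sum(W[v, own]) - gamma * length(own)
    if (cur < -tol) return(FALSE)  # new singleton would improve
    for (lab in setdiff(unique(sigma), sigma[v])) {
      idx <- which(sigma == lab)
      if (sum(W[v, idx]) - gamma * length(idx) > cur + tol) return(FALSE)
    }
  }
  TRUE
}

# exact k-mer sets on the string level (canonical option), independent of
# the hashing machinery
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

kmer_set <- function(seq, k, canonical = TRUE,
                     alphabet = c("A", "C", "G", "T")) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  ok <- !grepl(paste0("[^", paste(alphabet, collapse = ""), "]"), kmers)
  kmers <- kmers[ok]
  if (canonical)
    kmers <- vapply(kmers, function(x) min(x, revcomp(x)), character(1))
  unique(kmers)
}

exact_jaccard <- function(a, b, k, canonical = TRUE) {
  A <- kmer_set(a, k, canonical)
  B <- kmer_set(b, k, canonical)
  length(intersect(A, B)) / length(union(A, B))
}

# step-by-step replay of the binning rules, written directly from the
# ordering/score definitions
oracle_bin_replay <- function(raw, W, rho, gamma_low) {
  v <- sort(raw)
  prs <- t(combn(v, 2))
  w <- W[prs]
  ord <- order(-w, prs[, 1], prs[, 2])
  J <- integer(0)
  for (e in ord) {
    i <- prs[e, 1]; j <- prs[e, 2]
    if (!(i %in% J) && !(j %in% J)) {
      J <- if (rho[j] > rho[i]) c(J, j, i) else c(J, i, j)
    } else if (!(i %in% J)) J <- c(J, i)
    else if (!(j %in% J)) J <- c(J, j)
  }
  ibin <- function(B) {
    if (length(B) == 1) return(W[B, B])
    num <- 0; den <- 0
    for (x in B) { num <- num + rho[x] * (rho[x] - 1) / 2 * W[x, x]
                   den <- den + rho[x] * (rho[x] - 1) / 2 }
    for (xi in seq_along(B)) for (xj in seq_along(B)) if (xi < xj) {
      num <- num + rho[B[xi]] * rho[B[xj]] * W[B[xi], B[xj]]
      den <- den + rho[B[xi]] * rho[B[xj]]
    }
    num / den
  }
  iatt <- function(B, t) sum(rho[B] * W[B, t]) / sum(rho[B])
  bins <- list(J[1])
  for (t in J[-1]) {
    qs <- vapply(bins, function(B) 2 * iatt(B, t) - ibin(B) - gamma_low,
                 numeric(1))
    if (max(qs) > 0) {
      k <- which(qs == max(qs))[1]
      bins[[k]] <- c(bins[[k]], t)
    } else bins[[length(bins) + 1]] <- t
  }
  bins
}

# a graph with non-trivial rho, built by contracting a random primitive
# graph by a random partition (no sibling groups)
random_contracted_graph <- function(n_prim, n_groups, lo = 0.5, hi = 1) {
  W0 <- random_sim_matrix(n_prim, lo, hi)
  g <- init_graph(W0)
  sigma <- c(seq_len(n_groups),
             sample.int(n_groups, n_prim - n_groups, replace = TRUE))
  contract_graph(g, split(seq_len(n_prim), sigma))
}

hamming_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  mean(x == y)
}

# independent dynamic-programming oracle for the optimal ends-free
# (semi-global) alignment score under match 1 / mismatch -1 / linear gap 2
ends_free_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  # leading gaps free (zero first row/column); trailing gaps free (max over
  # last row/column)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- H[i, j] + if (x[i] == y[j]) match else mismatch
      H[i + 1, j + 1] <- max(d, H[i, j + 1] - gap, H[i + 1, j] - gap)
    }
  }
  max(H[n + 1, ], H[, m + 1])
}

# shared fixture for the end-to-end acceptance runs: 20 families with
# independent ancestors, 5-30 members, lengths 600-1200, per-site
# divergence 0.05
acceptance_families <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_families(n_families = 20, members = c(5, 30),
                                  length_range = c(600, 1200),
                                  divergence = 0.05, seed = 42)
    cache
  }
})
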