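#' Sketching parameters
#'
#' Parameters for bottom-s MinHash sketching of k-mers. The default k-mer
#' size is 17 for nucleotide sequences and 9 for complete proteins; 13 is
#' recommended for nucleotide datasets containing very short sequences.
#' The default sketch size is 2000.
#'
#' @param k k-mer length (1-32); `NULL` resolves to the alphabet default
#'   (17 nucleotide, 9 protein) when sketches are built.
#' @param sketch_size number of smallest distinct hash values retained.
#' @param canonical hash a nucleotide k-mer and its reverse complement as
#'   one (the lexicographically smaller strand is hashed); `NULL` resolves
#'   to `TRUE` for nucleotides, `FALSE` for proteins.
#' @param hash_seed fixed seed of the 64-bit hash, part of the sketch
#'   definition (sketches built with different seeds are incomparable).
#' @return An object of class `afc_sketch_params`.
#' @export
sketch_params <- function(k = NULL, sketch_size = 2000, canonical = NULL,
                          hash_seed = 42) {
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1 || k > 32) stop("k must be in 1..32")
  }
  sketch_size <- as.integer(sketch_size)
  if (sketch_size < 1) stop("sketch_size must be >= 1")
  structure(list(k = k, sketch_size = sketch_size, canonical = canonical,
                 hash_seed = as.integer(hash_seed)),
            class = "afc_sketch_params")
}

# Resolve alphabet-dependent defaults into concrete values.
resolve_sketch_params <- function(params, alphabet) {
  if (is.null(params$k))
    params$k <- if (alphabet == "nucleotide") 17L else 9L
  if (is.null(params$canonical))
    params$canonical <- alphabet == "nucleotide"
  params$alphabet_chars <- if (alphabet == "nucleotide") "ACGT"
                           else "ACDEFGHIKLMNPQRSTVWY"
  params
}

#' Build the bottom-s MinHash sketch of one sequence
#'
#' Enumerates all k-mers of the sequence, skips any containing a character
#' outside the strict alphabet (e.g. `N`, `X`), hashes each (canonically
#' for nucleotides) with a fixed-seed 64-bit hash, and keeps the
#' `sketch_size` smallest distinct values.
#'
#' @param residues a residue string, or an [afc_seqs] of length 1.
#' @param params an [sketch_params()] object.
#' @param alphabet `"nucleotide"` or `"protein"`; taken from `residues`
#'   when it is an `afc_seqs`.
#' @return A list of class `afc_sketch` with `hashes` (sorted, strictly
#'   increasing numeric vector) and `n_kmers` (distinct valid k-mers), and
#'   the resolved `k`, `sketch_size`, `canonical`, `hash_seed`.
#' @export
build_sketch <- function(residues, params = sketch_params(),
                         alphabet = NULL) {
  if (inherits(residues, "afc_seqs")) {
    if (length(residues) != 1) stop("build_sketch takes a single sequence")
    alphabet <- residues$alphabet
    residues <- residues$residues
  }
  if (is.null(alphabet)) stop("alphabet must be given for a bare string")
  p <- resolve_sketch_params(params, alphabet)
  if (nchar(residues) < p$k)
    stop("sequence shorter than k = ", p$k)
  sk <- sketch_cpp(toupper(residues), p$k, p$sketch_size, p$canonical,
                   p$hash_seed, p$alphabet_chars)
  structure(list(hashes = sk$hashes, n_kmers = sk$n_kmers, k = p$k,
                 sketch_size = p$sketch_size, canonical = p$canonical,
                 hash_seed = p$hash_seed),
            class = "afc_sketch")
}

check_compatible <- function(a, b) {
  if (a$k != b$k || a$sketch_size != b$sketch_size ||
      !identical(a$canonical, b$canonical) || a$hash_seed != b$hash_seed)
    stop("sketches were built with different parameters")
}

#' Mash distance between two sketches
#'
#' The Jaccard index `j` of the two k-mer sets is estimated from the
#' `sketch_size` smallest hash values of the union of the sketches; the
#' distance is `-log(2j / (1 + j)) / k`, clamped to `[0, 1]`, with
#' `j = 0` mapped to 1.
#'
#' @param a,b `afc_sketch` objects built with identical parameters.
#' @return A distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  check_compatible(a, b)
  j <- jaccard_sketch_cpp(a$hashes, b$hashes, a$sketch_size)
  if (j <= 0) return(1)
  min(max(-log(2 * j / (1 + j)) / a$k, 0), 1)
}

#' Pairwise similarity matrix of a sequence set
#'
#' Computes all pairwise Mash distances `d_ij` and returns the similarity
#' matrix `W = 1 - D` with unit diagonal (`w_ii = 1`, the vertex weight of
#' a singleton cluster; the graph has no self-loops).
#'
#' @param seqs an [afc_seqs] with at least 2 sequences, all of length
#'   at least `k`.
#' @param params an [sketch_params()] object.
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
build_similarity_matrix <- function(seqs, params = sketch_params()) {
  stopifnot(inherits(seqs, "afc_seqs"))
  if (length(seqs) < 2) stop("need at least 2 sequences")
  p <- resolve_sketch_params(params, seqs$alphabet)
  sketches <- lapply(seqs$residues, function(r)
    sketch_cpp(r, p$k, p$sketch_size, p$canonical, p$hash_seed,
               p$alphabet_chars))
  D <- mash_matrix_cpp(sketches, p$k, p$sketch_size)
  W <- 1 - D
  diag(W) <- 1
  dimnames(W) <- list(seqs$id, seqs$id)
  W
}
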