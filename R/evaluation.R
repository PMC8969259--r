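#' Select the representative center of a cluster
#'
#' Among members whose sequence length lies within
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the member lengths (quartiles by
#' linear interpolation), the member with the largest sum of similarities
#' to all other members is chosen. When no member satisfies the length
#' criteria, or the cluster has exactly two members, the longest sequence
#' is chosen. Ties are broken by the smallest id.
#'
#' @param ids character vector of member ids (length >= 2).
#' @param sim similarity submatrix of the members (dimnames optional,
#'   rows/cols in the order of `ids`).
#' @param seqs the [afc_seqs] the ids refer to.
#' @return The center id.
#' @export
select_center <- function(ids, sim, seqs) {
  if (length(ids) < 2) stop("center selection needs at least 2 members")
  len <- nchar(seqs$residues[match(ids, seqs$id)])
  pick_longest <- function() {
    cand <- ids[len == max(len)]
    sort(cand)[1]
  }
  if (length(ids) == 2) return(pick_longest())
  q <- quantile(len, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  ok <- len >= q[1] - 1.5 * iqr & len <= q[2] + 1.5 * iqr
  if (!any(ok)) return(pick_longest())
  sums <- rowSums(sim) - diag(sim)
  sums[!ok] <- -Inf
  cand <- ids[sums == max(sums)]
  sort(cand)[1]
}

#' Pairwise sequence identity from a semi-global alignment
#'
#' Aligns the two sequences globally with free end gaps and returns the
#' number of matched residues divided by the alignment length after
#' excluding terminal-gap columns. Scoring is match/mismatch +1/-1 with
#' linear gap cost 2 for nucleotides, and BLOSUM62 with gap open 11 /
#' extend 1 for proteins; identity depends on the alignment path only
#' through matched columns over retained columns.
#'
#' @param a,b residue strings of the same alphabet.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Identity in `[0, 1]` (0 when the aligned overlap is empty).
#' @export
pairwise_identity <- function(a, b, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  if (alphabet == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  }
  # overlap alignments clip terminal-gap columns from the aligned strings
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  if (length(ap) == 0) return(0)
  sum(ap == as_ & ap != "-") / length(ap)
}

#' Evaluate the non-singleton clusters of a result
#'
#' For every non-singleton cluster, pairwise identity is computed between
#' the representative center and every other member; the report records
#' the mean and minimum identity and the member attaining the minimum.
#' Singleton clusters produce no record.
#'
#' @param result an `afc_result`.
#' @param seqs the [afc_seqs] the clustering was run on.
#' @return A data frame with columns `cluster_index` (0-based, matching
#'   the cluster table), `center_id`, `size`, `mean_identity`,
#'   `min_identity`, `min_identity_partner`.
#' @export
evaluate_clusters <- function(result, seqs) {
  stopifnot(inherits(result, "afc_result"), inherits(seqs, "afc_seqs"))
  rows <- list()
  for (i in seq_along(result$clusters)) {
    members <- result$clusters[[i]]
    if (length(members) < 2) next
    center <- result$centers[i]
    others <- setdiff(members, center)
    res_center <- seqs$residues[match(center, seqs$id)]
    idents <- vapply(others, function(id)
      pairwise_identity(res_center, seqs$residues[match(id, seqs$id)],
                        seqs$alphabet), numeric(1))
    jmin <- which.min(idents)
    rows[[length(rows) + 1]] <- data.frame(
      cluster_index = i - 1L, center_id = center,
      size = length(members),
      mean_identity = mean(idents), min_identity = idents[jmin],
      min_identity_partner = others[jmin])
  }
  if (length(rows) == 0)
    return(data.frame(cluster_index = integer(0), center_id = character(0),
                      size = integer(0), mean_identity = numeric(0),
                      min_identity = numeric(0),
                      min_identity_partner = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cluster_index), ]
}

#' Write an evaluation report to CSV
#'
#' @param report data frame from [evaluate_clusters()].
#' @param path output CSV path.
#' @export
write_evaluation_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
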