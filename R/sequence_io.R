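#' Sequence set container
#'
#' A light container for a set of input sequences: ids, descriptions,
#' residue strings and the (single) alphabet of the dataset.
#'
#' @param ids character vector of unique, non-empty sequence ids.
#' @param residues character vector of residue strings (upper case).
#' @param descriptions optional character vector of free-text descriptions.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return An object of class `afc_seqs`.
#' @export
afc_seqs <- function(ids, residues, descriptions = ids,
                     alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  residues <- toupper(as.character(residues))
  if (length(ids) != length(residues))
    stop("ids and residues must have equal length")
  if (any(!nzchar(ids)))
    stop("sequence ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(nchar(residues) < 1))
    stop("zero-length sequence(s): ",
         paste(ids[nchar(residues) < 1], collapse = ", "))
  if (alphabet == "nucleotide")
    residues <- gsub("U", "T", residues, fixed = TRUE)
  structure(list(id = ids, description = as.character(descriptions),
                 residues = residues, alphabet = alphabet),
            class = "afc_seqs")
}

#' @export
length.afc_seqs <- function(x) length(x$id)

#' @export
`[.afc_seqs` <- function(x, i) {
  structure(list(id = x$id[i], description = x$description[i],
                 residues = x$residues[i], alphabet = x$alphabet),
            class = "afc_seqs")
}

#' @export
print.afc_seqs <- function(x, ...) {
  cat(sprintf("afc_seqs: %d %s sequence(s), lengths %d-%d\n",
              length(x), x$alphabet,
              min(nchar(x$residues)), max(nchar(x$residues))))
  invisible(x)
}

# Fraction of residues that look like nucleotides; >= 0.9 => nucleotide.
detect_alphabet <- function(residues) {
  chars <- strsplit(paste(residues, collapse = ""), "", fixed = TRUE)[[1]]
  frac_nt <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac_nt >= 0.9) "nucleotide" else "protein"
}

#' Read a multi-FASTA file
#'
#' Reads nucleotide or amino-acid sequences, upper-casing residues and
#' mapping `U` to `T` for nucleotides. The alphabet is auto-detected
#' (at least 90 percent of residues in `A,C,G,T,U,N` means nucleotide)
#' unless forced. Sequences shorter than the k-mer size `k`, when given,
#' cannot be sketched and are excluded with a warning naming their ids.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"` (default), `"nucleotide"` or `"protein"`.
#' @param k optional k-mer size used to filter too-short sequences.
#' @return An [afc_seqs] object with records in file order.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "protein"),
                       k = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  residues <- toupper(as.character(set))
  if (alphabet == "auto") alphabet <- detect_alphabet(residues)
  seqs <- afc_seqs(ids, residues, descriptions = headers, alphabet = alphabet)
  if (!is.null(k)) {
    short <- nchar(seqs$residues) < k
    if (any(short)) {
      warning("excluding ", sum(short), " sequence(s) shorter than k = ", k,
              ": ", paste(seqs$id[short], collapse = ", "))
      if (all(short)) stop("no sequences of length >= k = ", k, " remain")
      seqs <- seqs[!short]
    }
  }
  seqs
}

# Canonical cluster order: descending size, ties by smallest member id.
order_clusters <- function(clusters) {
  sizes <- lengths(clusters)
  first_id <- vapply(clusters, function(x) min(x), character(1))
  clusters[order(-sizes, first_id)]
}

#' Write a cluster membership table
#'
#' Writes one row per sequence with columns `cluster_index` (0-based),
#' `sequence_id` and `is_center` (1/0). Clusters are ordered by
#' descending size, ties broken by the lexicographically smallest member
#' id; members are listed center first, then lexicographically.
#'
#' @param result an `afc_result` from [af_cluster()].
#' @param path output path for the tab-separated table.
#' @export
write_cluster_table <- function(result, path) {
  stopifnot(inherits(result, "afc_result"))
  if (length(result$clusters) == 0) stop("empty cluster result")
  rows <- lapply(seq_along(result$clusters), function(i) {
    members <- sort(result$clusters[[i]])
    center <- result$centers[i]
    members <- c(center, setdiff(members, center))
    data.frame(cluster_index = i - 1L, sequence_id = members,
               is_center = as.integer(members == center))
  })
  tab <- do.call(rbind, rows)
  ok <- tryCatch({
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write cluster table to ", path)
  invisible(path)
}

#' Read a cluster membership table written by [write_cluster_table()]
#'
#' @param path path to the TSV table.
#' @return A list with `clusters` (list of id vectors in table order) and
#'   `centers` (one id per cluster).
#' @export
read_cluster_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "character", "integer"))
  idx <- sort(unique(tab$cluster_index))
  clusters <- lapply(idx, function(i) tab$sequence_id[tab$cluster_index == i])
  centers <- vapply(idx, function(i) {
    tab$sequence_id[tab$cluster_index == i & tab$is_center == 1][1]
  }, character(1))
  list(clusters = clusters, centers = centers)
}

#' Write representative (center) sequences to FASTA
#'
#' @param result an `afc_result`.
#' @param seqs the [afc_seqs] the clustering was run on.
#' @param path output FASTA path.
#' @export
write_representatives <- function(result, seqs, path) {
  stopifnot(inherits(result, "afc_result"), inherits(seqs, "afc_seqs"))
  pos <- match(result$centers, seqs$id)
  if (anyNA(pos)) stop("center id(s) absent from sequence set")
  set <- Biostrings::BStringSet(seqs$residues[pos])
  names(set) <- seqs$id[pos]
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
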