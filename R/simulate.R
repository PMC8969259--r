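#' Generate labelled synthetic homologous sequence families
#'
#' Draws one random ancestor per family and derives each member by i.i.d.
#' per-site substitutions (uniform over the alternative residues) plus
#' insertions/deletions with geometric lengths of mean 2. `divergence` is
#' the expected per-site divergence *between two family members*: each
#' member mutates at rate `divergence / 2` relative to the common
#' ancestor, so the mean pairwise within-family identity is approximately
#' `1 - divergence`. Ancestors of different families are independent, so
#' between-family identity sits at the random background. Ids encode the
#' family, which is also returned as a label table; output is
#' deterministic for a fixed seed.
#'
#' @param n_families number of families.
#' @param members length-2 range of members per family (drawn uniformly).
#' @param length_range length-2 range of ancestor lengths.
#' @param divergence expected per-site substitution divergence between
#'   two members of the same family, in `[0, 0.5)`.
#' @param indel_rate expected per-site rate of indel events separating
#'   two members (each member receives half).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param seed RNG seed.
#' @return A list with `seqs` (an [afc_seqs]) and `labels` (data frame
#'   with columns `id`, `class`).
#' @export
generate_families <- function(n_families = 20, members = c(5, 30),
                              length_range = c(600, 1200),
                              divergence = 0.05, indel_rate = 0.005,
                              alphabet = c("nucleotide", "protein"),
                              seed = 1) {
  alphabet <- match.arg(alphabet)
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must lie in [0, 0.5)")
  letters_ <- if (alphabet == "nucleotide") c("A", "C", "G", "T")
              else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  branch_div <- divergence / 2      # per member, so pairs differ at ~divergence
  branch_indel <- indel_rate / 2

  mutate <- function(anc) {
    x <- anc
    # substitutions: uniform over the alternative residues
    hit <- which(runif(length(x)) < branch_div)
    for (i in hit) {
      alt <- letters_[letters_ != x[i]]
      x[i] <- alt[sample.int(length(alt), 1)]
    }
    # indels: geometric length, mean 2; applied right-to-left so earlier
    # positions keep their meaning
    starts <- which(runif(length(x)) < branch_indel)
    for (i in rev(starts)) {
      len <- rgeom(1, 0.5) + 1
      if (runif(1) < 0.5) {
        x <- x[-(i:min(i + len - 1, length(x)))]
      } else {
        ins <- letters_[sample.int(length(letters_), len, replace = TRUE)]
        x <- append(x, ins, after = i)
      }
    }
    x
  }

  pick <- function(rng) {  # uniform over rng[1]..rng[2], safe for rng[1] == rng[2]
    vals <- seq(rng[1], rng[2])
    vals[sample.int(length(vals), 1)]
  }
  ids <- character(0); res <- character(0); cls <- character(0)
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%02d", f)
    L <- pick(length_range)
    anc <- letters_[sample.int(length(letters_), L, replace = TRUE)]
    m <- pick(members)
    for (s in seq_len(m)) {
      ids <- c(ids, sprintf("%s_S%03d", fam, s))
      res <- c(res, paste(mutate(anc), collapse = ""))
      cls <- c(cls, fam)
    }
  }
  list(seqs = afc_seqs(ids, res, alphabet = alphabet),
       labels = data.frame(id = ids, class = cls))
}

#' Labels as a class partition
#'
#' Turns a two-column label table (`id`, `class`) into the list-of-id-sets
#' form the validation indices expect.
#'
#' @param labels data frame with columns `id` and `class`.
#' @return List of id vectors, one per class.
#' @export
labels_to_classes <- function(labels) {
  unname(split(labels$id, labels$class))
}
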