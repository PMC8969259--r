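random_dna2 <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

test_that("two-member clusters take the longest sequence as center", {
  seqs <- afc_seqs(c("a", "b"), c(random_dna2(900), random_dna2(1000)))
  sim <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  expect_equal(select_center(c("a", "b"), sim, seqs), "b")
  # identical members: tie broken by smallest id
  seqs2 <- afc_seqs(c("b", "a"), rep(random_dna2(500), 2))
  expect_equal(select_center(c("b", "a"), sim, seqs2), "a")
})

test_that("length outliers are excluded before maximizing similarity sums", {
  ids <- paste0("s", 1:5)
  # s5 is an extreme length outlier but would win on similarity sum
  seqs <- afc_seqs(ids, c(random_dna2(500), random_dna2(510),
                          random_dna2(505), random_dna2(495),
                          random_dna2(5000)))
  sim <- matrix(0.8, 5, 5); diag(sim) <- 1
  sim[5, ] <- sim[, 5] <- 0.99; sim[5, 5] <- 1
  sim[2, ] <- pmax(sim[2, ], 0.85); sim[, 2] <- pmax(sim[, 2], 0.85)
  sim[2, 5] <- sim[5, 2] <- 0.99; sim[2, 2] <- 1
  expect_equal(select_center(ids, sim, seqs), "s2")
  expect_error(select_center("s1", sim[1, 1, drop = FALSE], seqs))
})

test_that("identity is 1 for equal sequences and for flush-end overlaps", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  # terminal-gap columns are trimmed: ACGT aligns flush right
  expect_equal(pairwise_identity("ACGT", "TTACGT"), 1)
  expect_equal(pairwise_identity("TTACGT", "ACGT"), 1)
  expect_error(pairwise_identity("", "ACGT"))
})

test_that("the alignment engine attains the dynamic-programming optimum", {
  set.seed(81)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (rep in 1:8) {
    a <- random_dna2(80)
    b <- if (rep %% 2 == 0) random_dna2(80) else {
      x <- strsplit(a, "")[[1]]
      hit <- runif(80) < 0.1
      x[hit] <- vapply(x[hit], function(c0)
        sample(setdiff(c("A", "C", "G", "T"), c0), 1), character(1))
      paste(x, collapse = "")
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    expect_equal(Biostrings::score(pa), ends_free_score(a, b),
                 tolerance = 1e-9)
  }
})

test_that("identity of mutated pairs tracks the per-site agreement", {
  set.seed(82)
  for (rep in 1:10) {
    a <- random_dna2(200)
    x <- strsplit(a, "")[[1]]
    hit <- runif(200) < 0.1
    hit[c(1:15, 186:200)] <- FALSE  # keep terminal runs intact
    x[hit] <- vapply(x[hit], function(c0)
      sample(setdiff(c("A", "C", "G", "T"), c0), 1), character(1))
    b <- paste(x, collapse = "")
    # the optimal path may trade a few mismatch columns for short internal
    # shifts, so identity can sit slightly above the per-site agreement
    expect_gte(pairwise_identity(a, b), hamming_identity(a, b) - 1e-12)
    expect_lt(pairwise_identity(a, b) - hamming_identity(a, b), 0.02)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("protein identity uses BLOSUM62 and handles identical chains", {
  aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE),
              collapse = "")
  expect_equal(pairwise_identity(aa, aa, alphabet = "protein"), 1)
})

test_that("evaluation reports cover exactly the non-singleton clusters", {
  set.seed(83)
  s <- random_dna2(300)
  seqs <- afc_seqs(c("a", "b", "c", "lone"),
                   c(s, s, s, random_dna2(300)))
  res <- af_cluster(seqs, sketch_params(k = 13), core_params(seed = 0))
  rep_df <- evaluate_clusters(res, seqs)
  n_nonsingleton <- sum(lengths(res$clusters) > 1)
  expect_equal(nrow(rep_df), n_nonsingleton)
  expect_false("lone" %in% rep_df$center_id)
  # identical members: mean = min = 1
  expect_equal(rep_df$mean_identity, rep(1, n_nonsingleton))
  expect_equal(rep_df$min_identity, rep(1, n_nonsingleton))
  expect_true(all(rep_df$min_identity <= rep_df$mean_identity))
  p <- tempfile(fileext = ".csv")
  write_evaluation_csv(rep_df, p)
  expect_equal(nrow(read.csv(p)), n_nonsingleton)
})

test_that("reported identities track the generator divergence", {
  sim <- generate_families(n_families = 3, members = c(4, 6),
                           length_range = c(800, 1000), divergence = 0.03,
                           indel_rate = 0, seed = 85)
  res <- af_cluster(sim$seqs, sketch_params(), core_params(seed = 0))
  rep_df <- evaluate_clusters(res, sim$seqs)
  # expected pairwise agreement for two branches of d/2 each
  d <- 0.03
  expected <- (1 - d / 2)^2 + (d / 2)^2 / 3
  expect_equal(mean(rep_df$mean_identity), expected, tolerance = 0.03)
})
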