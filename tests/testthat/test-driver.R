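random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

test_that("the resolution schedule is an exact decimal grid", {
  gs <- afclust:::gamma_schedule(core_params(0.95, 0.7, 0.025))
  expect_equal(gs[1], 0.95)
  expect_equal(gs[length(gs)], 0.70)  # last gamma > gamma_low - delta
  expect_equal(length(gs), 11)
  expect_equal(diff(gs), rep(-0.025, 10))
  gs2 <- afclust:::gamma_schedule(core_params(0.95, 0.75, 0.025))
  expect_equal(gs2[length(gs2)], 0.75)
})

test_that("identical sequences collapse to one cluster", {
  set.seed(61)
  s <- random_dna_str(100)
  seqs <- afc_seqs(paste0("s", 1:5), rep(s, 5))
  res <- af_cluster(seqs, sketch_params(k = 13), core_params(seed = 0))
  expect_length(res$clusters, 1)
  expect_setequal(res$clusters[[1]], seqs$id)
})

test_that("mutually dissimilar sequences stay singletons", {
  set.seed(63)
  seqs <- afc_seqs(paste0("s", 1:5),
                   replicate(5, random_dna_str(200)))
  res <- af_cluster(seqs, sketch_params(k = 17), core_params(seed = 0))
  expect_length(res$clusters, 5)
  expect_true(all(lengths(res$clusters) == 1))
})

test_that("a single sequence yields one singleton without a graph", {
  seqs <- afc_seqs("only", random_dna_str(100))
  res <- af_cluster(seqs, sketch_params(k = 13), core_params())
  expect_equal(res$clusters, list("only"))
  expect_equal(res$centers, "only")
})

test_that("too-short sequences are dropped and empty input is fatal", {
  seqs <- afc_seqs(c("ok", "tiny"), c(random_dna_str(100), "ACGTACGT"))
  expect_warning(res <- af_cluster(seqs, sketch_params(k = 13),
                                   core_params()), "tiny")
  expect_equal(unlist(res$clusters), "ok")
  short <- afc_seqs("tiny", "ACGT")
  expect_warning(expect_error(
    af_cluster(short, sketch_params(k = 13), core_params()), "remain"))
})

test_that("synthetic families are recovered exactly across gamma_low values", {
  sim <- generate_families(n_families = 5, members = c(3, 6),
                           length_range = c(400, 600), divergence = 0.04,
                           seed = 67)
  classes <- labels_to_classes(sim$labels)
  counts <- integer(0)
  for (gl in c(0.7, 0.75, 0.8)) {
    res <- af_cluster(sim$seqs, sketch_params(),
                      core_params(gamma_low = gl, seed = 0))
    expect_equal(nmi(res$clusters, classes), 1)
    counts <- c(counts, length(res$clusters))
  }
  expect_equal(length(unique(counts)), 1)  # gamma_low insensitivity
})

test_that("runs with a fixed seed are repeatable", {
  sim <- generate_families(n_families = 4, members = c(3, 5),
                           length_range = c(300, 500), seed = 69)
  r1 <- af_cluster(sim$seqs, sketch_params(), core_params(seed = 3))
  r2 <- af_cluster(sim$seqs, sketch_params(), core_params(seed = 3))
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$centers, r2$centers)
})

test_that("final non-singleton clusters stay above the soft cut-off", {
  sim <- generate_families(n_families = 4, members = c(4, 6),
                           length_range = c(400, 600), divergence = 0.06,
                           seed = 71)
  core <- core_params(gamma_low = 0.75, seed = 0)
  res <- af_cluster(sim$seqs, sketch_params(), core)
  W <- build_similarity_matrix(sim$seqs, sketch_params())
  for (cl in res$clusters) {
    if (length(cl) < 2) next
    sub <- W[cl, cl]
    expect_gt(mean(sub[upper.tri(sub)]), core$gamma_low)
  }
})

test_that("pre-clustering separates dissimilar groups and preserves results", {
  sim <- generate_families(n_families = 4, members = c(3, 5),
                           length_range = c(300, 500), seed = 73)
  parts <- precluster_partitions(sim$seqs, sketch_params(), 0.75)
  expect_gte(length(parts), 4)  # families share no similarity
  expect_setequal(unlist(parts), seq_len(length(sim$seqs)))
  # all-identical input collapses to one partition
  same <- afc_seqs(paste0("x", 1:4), rep(random_dna_str(80), 4))
  expect_length(precluster_partitions(same, sketch_params(k = 13), 0.75), 1)
  # forcing pre-clustering must not change the final clusters
  r_off <- af_cluster(sim$seqs, sketch_params(), core_params(seed = 0))
  r_on <- af_cluster(sim$seqs, sketch_params(), core_params(seed = 0),
                     precluster = TRUE)
  expect_identical(r_off$clusters, r_on$clusters)
})
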