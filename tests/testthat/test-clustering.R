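test_that("uncentered correlation distance has the right geometry", {
  x <- c(1, 2, 3)
  expect_equal(uncentered_correlation_distance(x, x), 0)
  expect_equal(uncentered_correlation_distance(x, -x), 2)
  expect_equal(uncentered_correlation_distance(c(1, 0), c(0, 1)), 1)
  # weighted: zero-weighted dimensions are invisible
  expect_equal(uncentered_correlation_distance(c(1, 0, 9), c(1, 0, -9),
                                               w = c(1, 1, 0)), 0)
  # pairwise-complete over NA dimensions
  expect_equal(uncentered_correlation_distance(c(1, NA, 2), c(1, 5, 2)), 0)
  expect_error(uncentered_correlation_distance(c(0, 0), c(1, 1)), "norm")
  expect_error(uncentered_correlation_distance(c(NA, 1), c(1, NA)),
               "pairwise-complete")
})

test_that("compute_item_weights down-weights dense neighbourhoods", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  expect_equal(compute_item_weights(d, cutoff = 0.8), rep(1, 3))
  d2 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3)  # items 1,2 duplicated
  w <- compute_item_weights(d2, cutoff = 0.8, exponent = 1)
  expect_equal(w[1:2], rep(0.5, 2))
  expect_true(all(w > 0))
})

test_that("average_linkage reproduces hand-computed UPGMA", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  h <- average_linkage(d)
  expect_equal(h$height, c(1, 4))
  expect_equal(h$merge[1, ], c(-2L, -1L))
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = list(c("x", "y"),
                                                        c("x", "y")))
  expect_equal(average_linkage(d2)$height, 0.7)
})

test_that("average_linkage matches the O(n^3) reference on random input", {
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(rnorm(12 * 4), 12)
    d <- as.matrix(dist(x))
    h <- average_linkage(d)
    ref <- upgma_brute(d)
    expect_equal(h$height, ref$heights, tolerance = 1e-12)
    # permutation invariance up to relabeling: same heights after shuffling
    p <- sample(12)
    h2 <- average_linkage(d[p, p])
    expect_equal(h2$height, h$height, tolerance = 1e-12)
  }
})

test_that("cut_clusters respects the cut and minimum size", {
  set.seed(5)
  x <- matrix(rnorm(20 * 3), 20)
  rownames(x) <- paste0("i", 1:20)
  d <- as.matrix(dist(x))
  dend <- average_linkage(d)
  one <- cut_clusters(dend, height = max(dend$height) + 1, min_size = 2)
  expect_length(one$clusters, 1L)
  none <- cut_clusters(dend, height = 0, min_size = 2)
  expect_length(none$clusters, 0L)
  expect_true(all(is.na(none$assignment)))
})

test_that("clustering recovers planted signature groups", {
  set.seed(6)
  centers <- matrix(0, 3, 40)
  centers[1, 1:10] <- 4; centers[2, 11:20] <- 4; centers[3, 21:30] <- -4
  truth <- rep(1:3, each = 20)
  z <- centers[truth, ] + matrix(rnorm(60 * 40), 60)
  rownames(z) <- sprintf("idr%02d", 1:60)
  d <- signature_distances(z)
  cut <- cut_clusters(average_linkage(d), k = 3, min_size = 5)
  expect_gte(adjusted_rand(cut$assignment[rownames(z)], truth), 0.9)
})

test_that("composition_kmeans is seeded and splits separated groups", {
  set.seed(7)
  freqz <- rbind(matrix(rnorm(40 * 20, 0), 40),
                 matrix(rnorm(40 * 20, 10), 40))
  rownames(freqz) <- paste0("s", 1:80)
  k1 <- composition_kmeans(freqz, K = 2, seed = 3)
  k2 <- composition_kmeans(freqz, K = 2, seed = 3)
  expect_identical(k1$assignment, k2$assignment)
  expect_equal(length(unique(k1$assignment[1:40])), 1L)
  expect_equal(length(unique(k1$assignment[41:80])), 1L)
  expect_false(k1$assignment[1] == k1$assignment[41])
  # K >= n: every item its own cluster
  kk <- composition_kmeans(freqz[1:5, ], K = 10)
  expect_equal(unname(kk$assignment), 1:5)
  expect_equal(kk$tot_withinss, 0)
})

test_that("aa_freq_zscores normalizes to the pool average", {
  seqs <- c(a = "AAAA", b = "CCCC", c = "AACC")
  z <- aa_freq_zscores(seqs)
  expect_equal(dim(z), c(3L, 20L))
  expect_equal(unname(colMeans(z)[c("A", "C")]), c(0, 0), tolerance = 1e-12)
})

test_that("similarity_control flags duplicated sequences only", {
  set.seed(8)
  seqs <- vapply(1:12, function(i) random_seq(60), character(1))
  names(seqs) <- paste0("q", 1:12)
  seqs["q2"] <- seqs["q1"]                  # exact duplicate pair
  assignment <- stats::setNames(rep(c("A", "B"), each = 6), names(seqs))
  pc <- similarity_control(assignment, seqs)
  expect_gte(pc["A"], 100 * 2 / 6 - 1e-9)   # both copies flagged
  expect_equal(unname(pc["B"]), 0)
  # singleton cluster reports 0
  a2 <- stats::setNames(c("S", rep("T", 11)), names(seqs))
  expect_equal(unname(similarity_control(a2, seqs)["S"]), 0)
})

test_that("annotate_query transfers the nearest cluster's annotations", {
  set.seed(9)
  z <- rbind(matrix(rnorm(10 * 8, 3), 10), matrix(rnorm(10 * 8, -3), 10))
  rownames(z) <- paste0("m", 1:20)
  assignment <- stats::setNames(rep(c("C1", "C2"), each = 10), rownames(z))
  centro <- colMeans(z[1:10, ])
  res <- annotate_query(centro, z, assignment,
                        cluster_annotations = list(C1 = "termA", C2 = "termB"))
  expect_equal(res$cluster, "C1")
  expect_equal(res$terms, "termA")
  expect_lt(res$distance, 0.1)
  # held-out members return to their own cluster
  correct <- 0
  for (i in 1:20) {
    a <- annotate_query(z[i, ], z[-i, ], assignment[-i])
    correct <- correct + (a$cluster == assignment[i])
  }
  expect_gte(correct / 20, 0.9)
})
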