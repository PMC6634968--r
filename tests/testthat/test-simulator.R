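model <- default_subst_model()

test_that("build_rate_matrix constructs a normalized reversible model", {
  u <- rep(1 / 20, 20); names(u) <- AA
  m <- build_rate_matrix(u, 1)
  offdiag <- m$Q[row(m$Q) != col(m$Q)]
  expect_equal(length(unique(round(offdiag, 12))), 1L)
  expect_equal(unname(rowSums(m$Q)), rep(0, 20), tolerance = 1e-12)
  # stationarity pi Q = 0 and unit expected rate
  expect_equal(max(abs(m$pi %*% m$Q)), 0, tolerance = 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  # same for a non-uniform model
  expect_equal(max(abs(model$pi %*% model$Q)), 0, tolerance = 1e-12)
  expect_equal(max(abs(model$pi * model$Q - t(model$pi * model$Q))), 0,
               tolerance = 1e-12)  # detailed balance of Q
  expect_error(build_rate_matrix(u * 2), "sum to 1")
  expect_error(build_rate_matrix(-u), "negative")
})

test_that("equal-rate model converges to uniform as t grows", {
  u <- rep(1 / 20, 20); names(u) <- AA
  m <- build_rate_matrix(u, 1)
  P <- model_P(m, 50)
  expect_equal(as.numeric(P), rep(1 / 20, 400), tolerance = 1e-8)
  expect_equal(model_P(m, 0), diag(20), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("estimate_stationary_freqs applies pseudocounts", {
  f <- estimate_stationary_freqs("AAAA")
  expect_equal(unname(f["A"]), 5 / 24)
  expect_equal(unname(f["C"]), 1 / 24)
  expect_equal(unname(estimate_stationary_freqs(paste(AA, collapse = ""))),
               rep(1 / 20, 20))
  expect_equal(unname(estimate_stationary_freqs(character(0))),
               rep(1 / 20, 20))
})

test_that("zero branch lengths reproduce the root at every leaf", {
  tr <- gen_tree(6, depth = 0, seed = 2)
  root <- random_seq(40, seed = 3)
  leaves <- evolve_sequence(root, tr, model, seed = 4)
  expect_true(all(leaves == root))
})

test_that("simulated end states match the transition kernel", {
  # fraction of changed sites vs 1 - sum_a pi_a P_aa(t) on a single branch
  root <- gen_root_idr(10000, composition = model$pi, seed = 5)
  tr <- newick_tree("(A:0.5,B:0);")
  for (t in c(0.1, 0.5, 1.0)) {
    tr$edge.length[tr$edge[, 2] == 1] <- t
    leaves <- evolve_sequence(root, tr, model, indels = NULL, seed = 6 + t)
    obs <- mean(strsplit(leaves[["A"]], "")[[1]] !=
                strsplit(root, "")[[1]])
    P <- model_P(model, t)
    expected <- 1 - sum(model$pi * diag(P))
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_lt(abs(obs - expected), 4 * se)
  }
})

test_that("long-time composition converges to stationary frequencies", {
  root <- paste(rep("A", 10000), collapse = "")
  tr <- newick_tree("(A:30,B:0);")
  leaves <- evolve_sequence(root, tr, model, indels = NULL, seed = 8)
  counts <- table(factor(strsplit(leaves[["A"]], "")[[1]], levels = AA))
  p <- suppressWarnings(stats::chisq.test(counts, p = model$pi)$p.value)
  expect_gt(p, 0.001)
})

test_that("indel lengths follow the truncated Zipf law", {
  m <- indel_model(alpha = 1.8, L_max = 50)
  set.seed(9)
  draws <- zipf_lengths(m, 10000)
  expect_true(all(draws >= 1 & draws <= 50))
  emp <- tabulate(draws, 50) / 10000
  # analytic mass function
  k <- 1:50; mass <- k^(-1.8) / sum(k^(-1.8))
  expect_lt(max(abs(cumsum(emp) - cumsum(mass))), 0.02)  # KS-style
})

test_that("masked residues survive every simulation", {
  root <- random_seq(60, seed = 10)
  mask <- rep(FALSE, 60); mask[6:13] <- TRUE
  tr <- gen_tree(6, depth = 1.5, seed = 11)
  heavy <- indel_model(lambda_ins = 0.08, lambda_del = 0.08)
  for (rep in 1:100) {
    leaves <- evolve_sequence(root, tr, model, indels = heavy, mask = mask,
                              seed = 1000 + rep)
    hom <- attr(leaves, "homology")
    for (h in hom) expect_true(all(6:13 %in% h))
  }
})

test_that("simulate_ensemble is seed-reproducible and counts non-empty", {
  tr <- gen_tree(5, depth = 1, seed = 12)
  root <- random_seq(30, seed = 13)
  e1 <- simulate_ensemble(root, tr, model, n = 3, seed = 14)
  e2 <- simulate_ensemble(root, tr, model, n = 3, seed = 14)
  expect_identical(e1$replicates, e2$replicates)
  expect_false(identical(e1$replicates[[1]], e1$replicates[[2]]))
  # deletion-heavy world: empties occur and are counted correctly
  del <- indel_model(lambda_ins = 0, lambda_del = 0.6, L_max = 30)
  root_s <- random_seq(12, seed = 15)
  ens <- simulate_ensemble(root_s, gen_tree(5, depth = 2, seed = 16), model,
                           indels = del, n = 40, seed = 17)
  manual <- sum(vapply(ens$replicates, function(r) all(nchar(r) > 0),
                       logical(1)))
  expect_equal(ens$n_nonempty, manual)
  expect_lt(ens$n_nonempty, 40)
})

test_that("filter_ensemble applies the non-empty boundary exactly", {
  fake <- function(n_ok, n_bad) {
    reps <- c(replicate(n_ok, c(a = "MK", b = "ML"), simplify = FALSE),
              replicate(n_bad, c(a = "", b = "ML"), simplify = FALSE))
    structure(list(idr_id = "x", replicates = reps, n_nonempty = n_ok,
                   nonempty = rep(c(TRUE, FALSE), c(n_ok, n_bad))),
              class = "sim_ensemble")
  }
  expect_false(is_rejected(filter_ensemble(fake(950, 50))))
  expect_true(is_rejected(filter_ensemble(fake(949, 51))))
  kept <- filter_ensemble(fake(960, 40))
  expect_length(kept$replicates, 960L)
})

test_that("calibrate_scaling normalizes the calibration-pair distance", {
  t1 <- newick_tree("(A:0.25,B:0.25);")   # distance 0.5
  t2 <- newick_tree("(A:0.75,B:0.75);")   # distance 1.5
  cal <- calibrate_scaling(list(t1, t2), "A", "B")
  expect_equal(cal$scale, 1.0)
  expect_equal(cal$post_mean, 1.0)
  t3 <- newick_tree("(A:0.5,B:0.5);"); t4 <- newick_tree("(A:1.5,B:1.5);")
  expect_equal(calibrate_scaling(list(t3, t4), "A", "B")$scale, 0.5)
  t5 <- newick_tree("(A:2,B:2);")
  expect_equal(calibrate_scaling(list(t5), "A", "B")$scale, 0.25)
  tx <- newick_tree("(C:1,D:1);")
  cal2 <- calibrate_scaling(list(t5, tx), "A", "B")
  expect_equal(cal2$n_skipped, 1L)
  expect_error(calibrate_scaling(list(tx), "A", "B"), "calibration taxa")
})
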