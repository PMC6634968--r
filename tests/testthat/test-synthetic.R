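test_that("gen_tree shapes and seeds are honoured", {
  t2 <- gen_tree(2, depth = 0.7, seed = 1)
  expect_equal(sum(t2$edge.length), 1.4)   # cherry: two depth-long branches
  expect_setequal(t2$tip.label, c("sp01", "sp02"))
  t0 <- gen_tree(6, depth = 0, seed = 2)
  expect_true(all(t0$edge.length == 0))
  expect_identical(ape::write.tree(gen_tree(8, 1, seed = 3)),
                   ape::write.tree(gen_tree(8, 1, seed = 3)))
  tr <- gen_tree(10, depth = 1.3, seed = 4)
  expect_equal(max(ape::node.depth.edgelength(tr)[1:10]), 1.3)
  expect_equal(attr(tr, "calibration"), c("sp01", "sp02"))
})

test_that("gen_root_idr draws the stated composition", {
  pure <- gen_root_idr(12, composition = c(Q = 1), seed = 5)
  expect_equal(pure, strrep("Q", 12))
  expect_equal(nchar(gen_root_idr(30, seed = 6)), 30L)
  comp <- default_subst_model()$pi
  big <- gen_root_idr(10000, composition = comp, seed = 7)
  freq <- table(factor(strsplit(big, "")[[1]], levels = AA)) / 10000
  se <- sqrt(comp * (1 - comp) / 10000)
  expect_true(all(abs(freq - comp) < 3.5 * se + 1e-9))
})

test_that("null ortholog sets diverge monotonically with depth", {
  root <- gen_root_idr(80, seed = 8)
  ident <- vapply(c(0.1, 0.5, 1, 2), function(d) {
    tr <- gen_tree(8, depth = d, seed = 9)
    os <- gen_null_ortholog_set(root, tr, seed = 10)
    rootch <- strsplit(root, "")[[1]]
    mean(vapply(seq_along(os$seqs), function(i) {
      hom <- os$homology[[i]]
      ch <- strsplit(os$seqs[[i]], "")[[1]]
      keep <- !is.na(hom)
      if (!any(keep)) return(0)
      mean(ch[keep] == rootch[hom[keep]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ident) < 0))
  # depth 0 reproduces the root exactly
  os0 <- gen_null_ortholog_set(root, gen_tree(8, depth = 0, seed = 11),
                               seed = 12)
  expect_true(all(os0$seqs == root))
})

test_that("masked residues survive in synthetic null sets", {
  root <- gen_root_idr(60, seed = 13)
  mask <- rep(FALSE, 60); mask[20:27] <- TRUE
  tr <- gen_tree(8, depth = 1.5, seed = 14)
  os <- gen_null_ortholog_set(root, tr, mask = mask, seed = 15)
  for (h in os$homology) expect_true(all(20:27 %in% h))
})

test_that("variance-clamp collapses the across-ortholog feature variance", {
  tr <- gen_tree(10, depth = 1, seed = 16)
  root <- gen_root_idr(80, seed = 17)
  nsd <- estimate_null_sd(root, tr, "scd", n = 15, seed = 18)
  expect_gt(nsd$sd, 0)
  fsc <- function(seqs) var(vapply(seqs, scd, numeric(1)))
  clamped <- nullvar <- numeric(12)
  for (i in 1:12) {
    cs <- gen_constrained_ortholog_set(root, tr, "scd",
                                       mode = "variance-clamp",
                                       tolerance = 0.5, null_sd = nsd$sd,
                                       seed = 100 + i)
    clamped[i] <- fsc(cs$seqs)
    ns <- gen_null_ortholog_set(root, tr, seed = 200 + i)
    nullvar[i] <- fsc(ns$seqs[nchar(ns$seqs) > 0])
  }
  expect_gte(mean(clamped < nullvar), 0.95)
})

test_that("infinite tolerance reproduces the null distribution", {
  tr <- gen_tree(8, depth = 1, seed = 19)
  root <- gen_root_idr(60, seed = 20)
  vals_c <- vals_n <- numeric(0)
  for (i in 1:10) {
    cs <- gen_constrained_ortholog_set(root, tr, "net_charge",
                                       mode = "variance-clamp",
                                       tolerance = Inf, null_sd = 1,
                                       seed = 300 + i)
    ns <- gen_null_ortholog_set(root, tr, seed = 400 + i)
    vals_c <- c(vals_c, vapply(cs$seqs, net_charge, numeric(1)))
    ns_ok <- ns$seqs[nchar(ns$seqs) > 0]
    vals_n <- c(vals_n, vapply(ns_ok, net_charge, numeric(1)))
  }
  expect_gt(suppressWarnings(ks.test(vals_c, vals_n)$p.value), 0.01)
})

test_that("mean-shift produces a detectable deviation from the null", {
  tr <- gen_tree(10, depth = 1, seed = 21)
  catalog <- default_catalog()
  flagged <- 0L
  for (i in 1:5) {
    root <- gen_root_idr(70, seed = 500 + i)
    nsd <- estimate_null_sd(root, tr, "net_charge", n = 12,
                            seed = 600 + i)
    cs <- gen_constrained_ortholog_set(root, tr, "net_charge",
                                       mode = "mean-shift", effect = 3,
                                       tolerance = 1.5, null_sd = nsd$sd,
                                       seed = 700 + i)
    ref <- cs$seqs[["sp01"]]
    expect_identical(ref, root)          # reference leaf stays unshifted
    ens <- simulate_ensemble(ref, tr, n = 500, seed = 800 + i)
    sig <- build_signature(summarize_set(cs$seqs, catalog),
                           ensemble_summaries(ens, catalog))
    if (!is.na(sig$p["mean_net_charge"]) &&
        sig$p["mean_net_charge"] < 0.01) flagged <- flagged + 1L
  }
  expect_gte(flagged, 4L)
})

test_that("gen_benchmark emits a coherent, seed-deterministic world", {
  spec <- benchmark_spec(n_classes = 2L, idrs_per_class = 4L, n_taxa = 6L,
                         root_length = 50L, seed = 42L)
  bm1 <- gen_benchmark(spec)
  bm2 <- gen_benchmark(spec)
  expect_identical(bm1$sets, bm2$sets)
  expect_length(bm1$sets, 8L)
  expect_equal(unname(table(bm1$truth)), c(4L, 4L), ignore_attr = TRUE)
  expect_setequal(names(bm1$idr2prot), names(bm1$sets))
  # planted terms cover their class more than the background
  ann <- bm1$annotations
  for (cls in names(bm1$planted_terms)) {
    for (tm in bm1$planted_terms[[cls]]) {
      inc <- bm1$idr2prot[names(bm1$truth)[bm1$truth == as.integer(cls)]]
      outc <- setdiff(bm1$idr2prot, inc)
      cov_in <- mean(inc %in% ann$protein_id[ann$term_id == tm])
      cov_out <- mean(outc %in% ann$protein_id[ann$term_id == tm])
      expect_gte(cov_in, cov_out)
    }
  }
})
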