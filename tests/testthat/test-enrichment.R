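test_that("map_idrs_to_proteins deduplicates within clusters", {
  idr2prot <- c(i1 = "P1", i2 = "P1", i3 = "P2", i4 = "P1")
  asg <- c(i1 = "A", i2 = "A", i3 = "A", i4 = "B")
  cp <- map_idrs_to_proteins(asg, idr2prot)
  expect_setequal(cp$A, c("P1", "P2"))
  expect_equal(cp$B, "P1")                 # same protein, second cluster
  asg2 <- c(i1 = "A", i2 = NA, i3 = NA, i4 = NA)
  expect_equal(map_idrs_to_proteins(asg2, idr2prot)$A, "P1")
})

test_that("filter_terms removes oversized GO terms at the boundary", {
  df <- rbind(data.frame(protein_id = sprintf("p%d", 1:5000),
                         term_id = "big5000", term_class = "GO"),
              data.frame(protein_id = sprintf("p%d", 1:5001),
                         term_id = "big5001", term_class = "GO"),
              data.frame(protein_id = sprintf("p%d", 1:5001),
                         term_id = "pheno", term_class = "phenotype"))
  tab <- annotation_table(df)
  out <- filter_terms(tab)
  expect_true("big5000" %in% out$term_id)
  expect_false("big5001" %in% out$term_id)
  expect_true("pheno" %in% out$term_id)    # non-GO classes untouched
  empty <- annotation_table(df[0, ])
  expect_equal(nrow(filter_terms(empty)), 0L)
})

test_that("hypergeom_test is the exact upper tail", {
  expect_equal(hypergeom_test(0, 4, 5, 10), 1)
  expect_equal(hypergeom_test(4, 4, 5, 10), 5 / 210)
  expect_error(hypergeom_test(5, 4, 5, 10), "inconsistent")
  # enumeration oracle over all k for N <= 15
  set.seed(1)
  for (rep in 1:20) {
    N <- sample(5:15, 1); n <- sample(1:N, 1); K <- sample(1:N, 1)
    for (k in 0:min(K, n))
      expect_equal(hypergeom_test(k, K, n, N), hyper_brute(k, K, n, N),
                   tolerance = 1e-12)
  }
})

test_that("bh_fdr is the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_equal(q, p.adjust(p, "BH"))       # independent reference
  expect_true(all(q >= p & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))   # monotone after sorting
})

test_that("enrich_clusters finds a planted association", {
  set.seed(3)
  prots <- sprintf("P%03d", 1:120)
  cluster <- list(C1 = prots[1:30], C2 = prots[31:60])
  ann <- annotation_table(rbind(
    data.frame(protein_id = c(prots[1:20], sample(prots[61:120], 3)),
               term_id = "planted", term_class = "GO"),
    data.frame(protein_id = sample(prots, 30), term_id = "noise",
               term_class = "GO")))
  res <- enrich_clusters(cluster, ann, background = prots)
  hit <- res[res$cluster == "C1" & res$term_id == "planted", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$k, 20L); expect_equal(hit$K, 30L)
  expect_equal(hit$n, 23L); expect_equal(hit$N, 120L)
  expect_lt(hit$q, 1e-6)
  expect_gte(hit$q, hit$p)
  full <- enrich_clusters(cluster, ann, background = prots, full = TRUE)
  expect_equal(nrow(full), 4L)             # 2 clusters x 2 terms
})

test_that("permutation_z separates planted from null clusters", {
  set.seed(4)
  n <- 160
  idrs <- sprintf("i%03d", 1:n)
  idr2prot <- stats::setNames(sprintf("P%03d", 1:n), idrs)
  planted_idrs <- idrs[1:40]
  ann <- annotation_table(rbind(
    data.frame(protein_id = c(idr2prot[planted_idrs[1:24]],   # 60% coverage
                              sample(idr2prot[idrs[41:160]], 6)),
               term_id = "T_planted", term_class = "GO"),
    data.frame(protein_id = sample(idr2prot, 25), term_id = "T_bg",
               term_class = "GO")))
  pz <- permutation_z(planted_idrs, idrs, idr2prot, ann, n_perm = 200,
                      seed = 9)
  expect_gt(pz$Z, 5)
  rand_idrs <- sample(idrs, 40)
  pz0 <- permutation_z(rand_idrs, idrs, idr2prot, ann, n_perm = 200,
                       seed = 10)
  expect_lt(abs(pz0$Z), 3)
  # determinism of the permutation null
  pz2 <- permutation_z(planted_idrs, idrs, idr2prot, ann, n_perm = 2,
                       seed = 11)
  pz3 <- permutation_z(planted_idrs, idrs, idr2prot, ann, n_perm = 2,
                       seed = 11)
  expect_identical(pz2$null_mean, pz3$null_mean)
})

test_that("composition-matched sampling needs cells and stays calibrated", {
  set.seed(5)
  n <- 80
  idrs <- sprintf("i%02d", 1:n)
  idr2prot <- stats::setNames(sprintf("P%02d", 1:n), idrs)
  ann <- annotation_table(
    data.frame(protein_id = sample(idr2prot, 20), term_id = "T1",
               term_class = "GO"))
  expect_error(permutation_z(idrs[1:10], idrs, idr2prot, ann,
                             sampler = "composition_matched"),
               "comp_assignment")
  # annotations independent of composition: both samplers near Z ~ 0
  cells <- stats::setNames(rep(1:4, each = 20), idrs)
  pu <- permutation_z(idrs[1:20], idrs, idr2prot, ann, n_perm = 150,
                      seed = 6)
  pc <- permutation_z(idrs[1:20], idrs, idr2prot, ann,
                      sampler = "composition_matched",
                      comp_assignment = cells, n_perm = 150, seed = 6)
  expect_lt(abs(pu$Z), 3)
  expect_lt(abs(pc$Z), 3)
})
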