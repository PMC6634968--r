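catalog <- default_catalog()

test_that("the default catalog has 82 uniquely named features", {
  expect_length(catalog, 82L)
  expect_false(anyDuplicated(catalog_names(catalog)) > 0)
})

test_that("compute_features covers the catalog and is deterministic", {
  f <- compute_features("QQQQ", catalog)
  expect_length(f, 82L)
  expect_equal(unname(f["frac_Q"]), 1.0)
  expect_equal(unname(f["net_charge"]), 0)
  expect_equal(unname(f["wf_complexity"]), 0)
  expect_identical(f, compute_features("QQQQ", catalog))
  # catalog order permutation does not change values
  perm <- sample(seq_along(catalog))
  f2 <- compute_features("QQQQ", structure(catalog[perm],
                                           class = "feature_catalog"))
  expect_equal(f2[names(f)], f)
  expect_error(compute_features("QQ-Q"), "gap")
  expect_length(compute_features("QQQQ",
                                 structure(list(),
                                           class = "feature_catalog")), 0L)
})

test_that("compute_features agrees with the single-feature operations", {
  s <- "EKEKSPARQQQQKKKKDDDD"
  f <- compute_features(s, catalog)
  expect_equal(unname(f["frac_E"]), aa_fraction(s, "E"))
  expect_equal(unname(f["net_charge"]), net_charge(s))
  expect_equal(unname(f["scd"]), scd(s))
  expect_equal(unname(f["kappa"]), patterning(s, "kappa"))
  expect_equal(unname(f["omega"]), patterning(s, "omega"))
  expect_equal(unname(f["wf_complexity"]), wf_complexity(s))
  expect_equal(unname(f["isoelectric_point"]), isoelectric_point(s))
  expect_equal(unname(f["hydrophobicity_kd"]), hydrophobicity(s))
  expect_equal(unname(f["motif_pdir"]), motif_density(s, "[ST]P"))
  expect_equal(unname(f["rep_Q"]), repeat_density(s, "Q"))
})

test_that("aa_fraction counts residue sets", {
  expect_equal(aa_fraction("NNNA", "N"), 0.75)
  expect_equal(aa_fraction(random_seq(30, seed = 1), AA), 1.0)
  expect_equal(aa_fraction("DEKR", c("D", "E")), 0.5)
})

test_that("net_charge handles signs and phosphosites", {
  expect_equal(net_charge("DDKK"), 0)
  expect_equal(net_charge("KRKR"), 4)
  expect_equal(net_charge("SKKK", phospho_sites = 0), 1)  # 3 - 2
  expect_equal(net_charge("HHHH"), 0)                     # H contributes 0
})

test_that("scd matches hand values and brute force", {
  expect_equal(scd("AAAA"), 0)
  expect_equal(scd("EK"), -0.5)
  expect_equal(scd("KK"), 0.5)
  set.seed(3)
  for (i in 1:20) {
    s <- random_seq(sample(4:12, 1), pool = c("E", "K", "A"))
    expect_equal(scd(s), scd_brute(s))
  }
})

test_that("patterning is normalized, handles undefined compositions", {
  expect_equal(patterning("EEEEEEKKKKKK", "kappa"), 1.0)
  expect_true(is.na(patterning("GGGGGG", "kappa")))
  v <- patterning("EKEKEKEK", "kappa")
  expect_lt(v, 0.1)
  expect_equal(v, kappa_brute("EKEKEKEK"))
  expect_true(is.na(patterning("GGGG", "omega")))   # no {P, charged}
  expect_false(is.na(patterning("GPGGGG", "omega")))
})

test_that("scd and kappa agree with brute force on short {E,K,A} sequences", {
  pool <- c("E", "K", "A")
  for (L in 2:6) {
    combos <- expand.grid(rep(list(pool), L), stringsAsFactors = FALSE)
    seqs <- apply(combos, 1, paste, collapse = "")
    for (s in seqs) {
      expect_equal(scd(s), scd_brute(s), tolerance = 1e-12)
      expect_equal(patterning(s, "kappa"), kappa_brute(s), tolerance = 1e-12)
    }
  }
})

test_that("composition features are permutation-invariant, patterning not", {
  s <- "EEEEKKKKAAAAPPPPSSSS"
  set.seed(9)
  shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  for (feat in c("frac_E", "net_charge", "wf_complexity",
                 "isoelectric_point", "hydrophobicity_kd")) {
    f1 <- compute_features(s, catalog)[feat]
    f2 <- compute_features(shuf, catalog)[feat]
    expect_equal(unname(f1), unname(f2), tolerance = 1e-10)
  }
  expect_false(isTRUE(all.equal(patterning(s, "kappa"),
                                patterning(shuf, "kappa"))))
})

test_that("wf_complexity entropy form is bounded and exact", {
  expect_equal(wf_complexity("AAAA"), 0)
  expect_equal(wf_complexity(paste(AA, collapse = "")), 1.0)
  expect_equal(wf_complexity("AADD"), log(2, base = 20))
  # K1 multinomial form is also available
  expect_lt(wf_complexity("AADD", form = "k1"), wf_complexity("AADD"))
})

test_that("isoelectric_point behaves like a pI", {
  expect_gt(isoelectric_point("KKKK"), 10)
  expect_lt(isoelectric_point("DDDD"), 4.5)
  set.seed(11)
  for (i in 1:10) {
    s <- random_seq(sample(5:30, 1))
    expect_gte(isoelectric_point(paste0(s, "K")) + 1e-6,
               isoelectric_point(s))
  }
})

test_that("motif_density counts overlapping anchors and respects masks", {
  expect_equal(motif_density("SPAR", "[ST]P"), 0.25)
  expect_equal(motif_density("SPAR", "[ST]P",
                             mask = c(TRUE, FALSE, FALSE, FALSE)), 0)
  expect_equal(motif_density("SPSP", "[ST]P"), 0.5)
  expect_equal(motif_density("SSSS", "SS"), 0.75)  # overlapping matches
})

test_that("repeat_density counts residues in qualifying runs", {
  expect_equal(repeat_density("QQQQA", "Q"), 0.8)
  expect_equal(repeat_density("QAQAQA", "Q"), 0)
  expect_equal(repeat_density("KKKKKAKKKK", "K"), 0.9)
  expect_equal(repeat_density("DEDEADDDD", c("D", "E")), 8 / 9)
})

test_that("hydrophobicity is the scale mean", {
  expect_equal(hydrophobicity("IIII"), 4.5)
  expect_equal(hydrophobicity("RRRR"), -4.5)
  expect_equal(hydrophobicity("IR"), 0)
})

test_that("fraction-family features lie in [0,1]; length equals length", {
  set.seed(13)
  fams <- vapply(catalog, `[[`, character(1), "family")
  for (i in 1:5) {
    s <- random_seq(sample(15:60, 1))
    f <- compute_features(s, catalog)
    fr <- f[fams == "composition"]
    expect_true(all(fr >= 0 & fr <= 1))
    expect_equal(unname(f["length"]), nchar(s))
  }
})

test_that("catalog config round-trips through JSON", {
  f <- tempfile(fileext = ".json")
  write_catalog_config(catalog, f)
  back <- read_catalog_config(f)
  expect_equal(catalog_names(back), catalog_names(catalog))
  s <- random_seq(40, seed = 21)
  expect_equal(compute_features(s, back), compute_features(s, catalog))
})
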