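# Synthetic data generation: random phylogenies, root IDRs, null and
# constraint-carrying ortholog sets (stabilizing selection emulated by
# rejection sampling of branch outcomes), and annotation tables with planted
# cluster-term associations. Everything is a pure function of (spec, seed).

#' Generate a random ultrametric phylogeny
#'
#' Coalescent-style topology rescaled so root-to-tip depth equals `depth`
#' (calibrated units, so the two calibration taxa sit at patristic distance
#' up to `2 * depth`). Tips are `sp01..spNN`; the first two are the
#' designated calibration taxa (attribute `"calibration"`).
#'
#' @param n_taxa number of tips (>= 2).
#' @param depth root-to-tip depth.
#' @param seed integer seed.
#' @return `ape::phylo` tree.
#' @export
gen_tree <- function(n_taxa, depth = 1, seed) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  set.seed(seed)
  labels <- sprintf("sp%02d", seq_len(n_taxa))
  tr <- ape::rcoal(n_taxa, tip.label = labels)
  tipdepth <- max(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
  tr$edge.length <- if (tipdepth > 0) tr$edge.length * depth / tipdepth
                    else tr$edge.length * 0
  attr(tr, "calibration") <- labels[1:2]
  tr
}

#' Generate a random root IDR sequence
#'
#' @param length sequence length (exact).
#' @param composition named residue frequencies (default: the disorder model
#'   stationary frequencies).
#' @param seed integer seed.
#' @return ungapped amino-acid string.
#' @export
gen_root_idr <- function(length, composition = NULL, seed) {
  if (is.null(composition)) composition <- default_subst_model()$pi
  p <- rep(0, 20L); names(p) <- AA20
  p[names(composition)] <- composition
  set.seed(seed)
  paste(sample(AA20, length, replace = TRUE, prob = p), collapse = "")
}

#' Generate a null ortholog set with its true homology map
#'
#' A thin wrapper over [evolve_sequence()] that keeps the residue-homology
#' ground truth, for rate-model and mask-protection tests.
#'
#' @inheritParams evolve_sequence
#' @return list: `seqs` (named ungapped sequences), `homology` (per tip,
#'   root position of each residue; NA = insertion), `root`.
#' @export
gen_null_ortholog_set <- function(root, tree, model = default_subst_model(),
                                  rates = 1, indels = indel_model(),
                                  scale = 1, mask = NULL, seed) {
  leaves <- evolve_sequence(root, tree, model, rates, indels, scale, mask,
                            seed = seed)
  list(seqs = stats::setNames(as.character(leaves), names(leaves)),
       homology = attr(leaves, "homology"), root = root)
}

# fast single-feature evaluator from a catalog definition
single_feature_fn <- function(feature, catalog = default_catalog()) {
  nm <- catalog_names(catalog)
  if (!feature %in% nm) stop("feature not in catalog: ", feature)
  def <- catalog[[match(feature, nm)]]
  function(seq) {
    ch <- aa_chars(seq)
    ctx <- list(seq = seq, ch = ch, L = length(ch), counts = aa_counts(ch),
                nplus = sum(ch %in% POSITIVE), nminus = sum(ch %in% NEGATIVE),
                runs = rle(ch), mask = NULL)
    eval_feature(def, ctx)
  }
}

#' Leaf-level null spread of a feature
#'
#' Simulates `n` null ortholog sets and returns the standard deviation of
#' the feature over all leaves — the "null sigma" unit in which planted
#' effect sizes and tolerances are expressed.
#'
#' @inheritParams gen_null_ortholog_set
#' @param feature catalog feature name.
#' @param catalog a `feature_catalog`.
#' @param n number of null sets (default 25).
#' @return list: `sd`, `root_value`.
#' @export
estimate_null_sd <- function(root, tree, feature,
                             catalog = default_catalog(),
                             model = default_subst_model(),
                             indels = indel_model(), scale = 1, n = 25L,
                             seed) {
  ffun <- single_feature_fn(feature, catalog)
  vals <- numeric(0)
  for (i in seq_len(n)) {
    s <- gen_null_ortholog_set(root, tree, model, 1, indels, scale,
                               seed = derive_seed(seed, i))$seqs
    s <- s[nchar(s) > 0L]
    vals <- c(vals, vapply(s, ffun, numeric(1L)))
  }
  list(sd = stats::sd(vals, na.rm = TRUE), root_value = ffun(root))
}

# greedy hill-climb: random substitutions accepted when they move the
# feature toward `target`; used to build the shifted ancestral state
shift_sequence_feature <- function(root, ffun, target, tol, budget = 4000L) {
  aa <- encode_seq(root)
  cur <- ffun(decode_seq(aa))
  for (i in seq_len(budget)) {
    if (!is.na(cur) && abs(cur - target) <= tol) return(decode_seq(aa))
    pos <- sample.int(length(aa), 1L)
    new <- aa
    new[pos] <- sample.int(20L, 1L)
    v <- ffun(decode_seq(new))
    if (!is.na(v) && (is.na(cur) || abs(v - target) < abs(cur - target))) {
      aa <- new; cur <- v
    }
  }
  stop("could not construct an ancestral sequence with feature value ",
       format(target), " (reached ", format(cur), ")")
}

#' Generate an ortholog set evolving under a planted feature constraint
#'
#' Emulates stabilizing (or directional) selection on one molecular feature
#' without modifying the substitution process: every branch outcome is
#' rejection-sampled until the child's feature value lies within
#' `tolerance * null_sd` of the target.
#'
#' * `variance-clamp`: target = the root's feature value; across-ortholog
#'   variance collapses relative to the null.
#' * `mean-shift`: target = root value + `effect * null_sd`. Because a
#'   multi-sigma shift is unreachable by rejection from null branch
#'   outcomes alone, the simulation starts from a shifted ancestral state
#'   (greedy feature-directed substitutions on the root) and the reference
#'   species' leaf is replaced by the unshifted root, so the orthologs
#'   deviate from a null that is re-rooted at the reference sequence.
#'
#' @inheritParams gen_null_ortholog_set
#' @param feature catalog feature name the constraint acts on.
#' @param catalog a `feature_catalog`.
#' @param mode `"variance-clamp"` or `"mean-shift"`.
#' @param effect effect size in null-sd units (mean-shift only).
#' @param tolerance acceptance half-width in null-sd units.
#' @param null_sd leaf-level null sd of the feature (estimated via
#'   [estimate_null_sd()] when NULL).
#' @param reference_species leaf kept equal to the unshifted root under
#'   mean-shift (default: first tip).
#' @param budget rejection attempts per branch before giving up.
#' @return list: `seqs`, `root`, `target`, `null_sd`, `mode`, `feature`.
#' @export
gen_constrained_ortholog_set <- function(root, tree, feature,
                                         catalog = default_catalog(),
                                         mode = c("variance-clamp",
                                                  "mean-shift"),
                                         effect = 0, tolerance = 1,
                                         null_sd = NULL,
                                         model = default_subst_model(),
                                         indels = indel_model(), scale = 1,
                                         reference_species = NULL,
                                         budget = 200L, seed) {
  mode <- match.arg(mode)
  ffun <- single_feature_fn(feature, catalog)
  if (is.null(null_sd))
    null_sd <- estimate_null_sd(root, tree, feature, catalog, model, indels,
                                scale, seed = derive_seed(seed, 9999L))$sd
  if (!is.finite(null_sd) || null_sd <= 0)
    stop("null_sd for feature '", feature, "' is not positive")
  set.seed(seed)
  v0 <- ffun(root)
  ntip <- length(tree$tip.label)
  # the reference leaf stays at the root value, diluting the realized
  # across-ortholog shift by (n-1)/n; compensate in the target
  target <- if (mode == "mean-shift")
    v0 + effect * null_sd * ntip / (ntip - 1) else v0
  ancestor <- root
  if (mode == "mean-shift" && effect != 0)
    ancestor <- shift_sequence_feature(root, ffun, target,
                                       tolerance * null_sd / 2)
  st0 <- root_state(ancestor, 1, NULL)
  getP <- make_p_cache(model)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  states <- vector("list", max(tree$edge))
  states[[ntip + 1L]] <- st0
  tolabs <- tolerance * null_sd
  # greedy compensatory substitutions pulling the feature back to target;
  # triggered when drift leaves the tolerance window, repairs to well
  # inside it (tol/4) so leaves do not pile up at the window edge that
  # mean reversion pushes them toward
  repair <- function(st) {
    # single substitutions move ratio-type features in steps of ~1/L, so
    # the settle threshold cannot be finer than that granularity
    gran <- 1.5 / length(st$aa)
    cur <- ffun(decode_seq(st$aa))
    if (!is.na(cur) && abs(cur - target) <= max(tolabs / 2, gran)) return(st)
    for (i in seq_len(budget * 20L)) {
      if (!is.na(cur) && abs(cur - target) <= max(tolabs / 4, gran))
        return(st)
      pos <- sample.int(length(st$aa), 1L)
      old <- st$aa[pos]
      st$aa[pos] <- sample.int(20L, 1L)
      v <- ffun(decode_seq(st$aa))
      if (is.na(v) || (!is.na(cur) && abs(v - target) >= abs(cur - target)))
        st$aa[pos] <- old
      else cur <- v
    }
    NULL
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t_e <- tree$edge.length[e]
    if (mode == "mean-shift" && !is.infinite(tolabs)) {
      # continual selection: simulate in short segments; after each, apply
      # compensatory substitutions whenever drift leaves the target window
      # (pure rejection cannot hold a multi-sigma shift against the
      # mean reversion of the substitution process)
      st <- states[[parent]]
      nseg <- max(1L, ceiling(t_e * scale / 0.1))
      okseg <- TRUE
      for (sgi in seq_len(nseg)) {
        st <- sim_branch(st, t_e / nseg, model, indels, scale, 1, getP)
        if (length(st$aa) == 0L) { okseg <- FALSE; break }
        st <- repair(st)
        if (is.null(st)) { okseg <- FALSE; break }
      }
      if (!okseg)
        stop("constraint infeasible: feature '", feature,
             "' mode mean-shift target ", format(target), " tolerance ",
             format(tolabs))
      states[[child]] <- st
    } else {
      ok <- FALSE
      for (try in seq_len(budget)) {
        cand <- sim_branch(states[[parent]], t_e, model, indels, scale, 1,
                           getP)
        if (length(cand$aa) == 0L) next
        v <- ffun(decode_seq(cand$aa))
        if (is.infinite(tolabs) ||
            (!is.na(v) && abs(v - target) <= tolabs)) {
          states[[child]] <- cand; ok <- TRUE; break
        }
      }
      if (!ok)
        stop("constraint infeasible: feature '", feature, "' mode ", mode,
             " target ", format(target), " tolerance ", format(tolabs),
             " (budget ", budget, " exhausted on a branch)")
    }
  }
  seqs <- vapply(seq_len(ntip), function(i) decode_seq(states[[i]]$aa),
                 character(1L))
  names(seqs) <- tree$tip.label
  if (mode == "mean-shift") {
    if (is.null(reference_species))
      reference_species <- sort(tree$tip.label)[1L]
    seqs[reference_species] <- root
  }
  list(seqs = seqs, root = root, target = target, null_sd = null_sd,
       mode = mode, feature = feature)
}

#' Specification of a planted benchmark dataset
#'
#' Defaults state the benchmark's world once: 16 taxa at calibrated depth 1,
#' 100-residue roots drawn from the disorder composition, 3 constraint
#' classes of 40 IDRs, 2 planted terms per class at 60% in-class / 5%
#' background coverage — sized to run in minutes on one CPU.
#'
#' @param n_classes number of constraint classes.
#' @param idrs_per_class IDRs per class.
#' @param profiles per-class constraint list(feature, mode, effect,
#'   tolerance); defaults plant 4-sigma mean shifts on net charge,
#'   hydropathy, and glutamine content (three distinct signature
#'   directions).
#' @param n_taxa,depth tree shape.
#' @param root_length root IDR length.
#' @param terms_per_class planted annotation terms per class.
#' @param coverage in-class annotation probability.
#' @param background_coverage out-of-class annotation probability.
#' @param n_noise_terms unplanted terms annotated uniformly at
#'   `background_coverage`.
#' @param seed integer seed.
#' @return list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_classes = 3L, idrs_per_class = 40L,
                           profiles = NULL, n_taxa = 16L, depth = 1,
                           root_length = 100L, terms_per_class = 2L,
                           coverage = 0.6, background_coverage = 0.05,
                           n_noise_terms = 5L, seed = 1L) {
  if (is.null(profiles))
    profiles <- list(
      list(feature = "net_charge", mode = "mean-shift", effect = 4,
           tolerance = 1.5),
      list(feature = "hydrophobicity_kd", mode = "mean-shift", effect = 4,
           tolerance = 1.5),
      list(feature = "frac_Q", mode = "mean-shift", effect = 4,
           tolerance = 1.5))
  profiles <- rep_len(profiles, n_classes)
  structure(list(n_classes = n_classes, idrs_per_class = idrs_per_class,
                 profiles = profiles, n_taxa = n_taxa, depth = depth,
                 root_length = root_length,
                 terms_per_class = terms_per_class, coverage = coverage,
                 background_coverage = background_coverage,
                 n_noise_terms = n_noise_terms, seed = seed),
            class = "benchmark_spec")
}

#' Generate a full planted benchmark dataset
#'
#' Realizes each class with [gen_constrained_ortholog_set()] (null-sd
#' estimated once per class on its first root), assigns each class its
#' planted terms at the stated coverages, and emits truth labels for
#' clustering (ARI) and enrichment-recovery scoring.
#'
#' @param spec a `benchmark_spec`.
#' @param model,indels,scale evolution model (defaults as elsewhere).
#' @return list: `tree`, `sets` (idr -> named seq vector), `roots`, `truth`
#'   (idr -> class), `idr2prot`, `annotations` (`annotation_table`),
#'   `planted_terms` (class -> term ids), `spec`.
#' @export
gen_benchmark <- function(spec = benchmark_spec(),
                          model = default_subst_model(),
                          indels = indel_model(), scale = 1) {
  seed <- spec$seed
  tree <- gen_tree(spec$n_taxa, spec$depth, seed = derive_seed(seed, 1L))
  n_idr <- spec$n_classes * spec$idrs_per_class
  idr_ids <- sprintf("idr%03d", seq_len(n_idr))
  truth <- rep(seq_len(spec$n_classes), each = spec$idrs_per_class)
  names(truth) <- idr_ids
  sets <- roots <- vector("list", n_idr)
  names(sets) <- names(roots) <- idr_ids
  null_sd_by_class <- numeric(spec$n_classes)
  for (i in seq_len(n_idr)) {
    cls <- truth[i]
    prof <- spec$profiles[[cls]]
    root <- gen_root_idr(spec$root_length, seed = derive_seed(seed, 100L + i))
    if (i == (cls - 1L) * spec$idrs_per_class + 1L)
      null_sd_by_class[cls] <- estimate_null_sd(
        root, tree, prof$feature, model = model, indels = indels,
        scale = scale, seed = derive_seed(seed, 500L + cls))$sd
    cs <- gen_constrained_ortholog_set(
      root, tree, prof$feature, mode = prof$mode, effect = prof$effect,
      tolerance = prof$tolerance, null_sd = null_sd_by_class[cls],
      model = model, indels = indels, scale = scale,
      seed = derive_seed(seed, 1000L + i))
    sets[[i]] <- cs$seqs
    roots[[i]] <- root
  }
  prot_ids <- sprintf("P%03d", seq_len(n_idr))   # one protein per IDR
  idr2prot <- stats::setNames(prot_ids, idr_ids)
  set.seed(derive_seed(seed, 7L))
  rows <- list()
  planted <- list()
  for (cls in seq_len(spec$n_classes)) {
    terms <- sprintf("T_class%d_%d", cls, seq_len(spec$terms_per_class))
    planted[[as.character(cls)]] <- terms
    in_class <- prot_ids[truth == cls]
    out_class <- prot_ids[truth != cls]
    for (tm in terms) {
      hits <- c(in_class[stats::runif(length(in_class)) < spec$coverage],
                out_class[stats::runif(length(out_class)) <
                          spec$background_coverage])
      if (length(hits))
        rows[[length(rows) + 1L]] <- data.frame(protein_id = hits,
                                                term_id = tm,
                                                term_class = "GO")
    }
  }
  for (j in seq_len(spec$n_noise_terms)) {
    hits <- prot_ids[stats::runif(n_idr) < spec$background_coverage]
    if (length(hits))
      rows[[length(rows) + 1L]] <- data.frame(protein_id = hits,
                                              term_id = sprintf("T_noise_%d", j),
                                              term_class = "GO")
  }
  annotations <- annotation_table(do.call(rbind, rows))
  list(tree = tree, sets = sets, roots = roots, truth = truth,
       idr2prot = idr2prot, annotations = annotations,
       planted_terms = planted, spec = spec)
}
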