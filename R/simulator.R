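# Null evolution of an IDR along a phylogeny: exact CTMC substitution
# sampling per site via cached P(t) matrices, Poisson power-law indels, and
# absolute protection of conserved-segment (masked) residues from deletion.

#' Derive a replicate seed from a master seed
#'
#' Deterministic Lehmer-style mixing of `(seed, i)`; the result always fits
#' a 32-bit integer, so derived seeds are safe for [set.seed()].
#'
#' @param seed master integer seed.
#' @param i replicate / stream index.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, i) {
  # exact in doubles: (seed mod p) * 48271 < 2^53; result kept below 2^31
  as.integer(((as.double(seed) %% 2147483647) * 48271 + 104729 * i) %%
               2147483647)
}

encode_seq <- function(seq) match(aa_chars(seq), AA20)
decode_seq <- function(x) paste(AA20[x], collapse = "")

make_p_cache <- function(model) {
  pcache <- new.env(parent = emptyenv())
  function(t) {
    key <- format(t, digits = 12)
    if (is.null(pcache[[key]])) {
      P <- model_P(model, t)
      pcache[[key]] <- list(P = P, cum = t(apply(P, 1L, cumsum)))
    }
    pcache[[key]]
  }
}

# evolve one branch: st is list(aa, rate, mask, hom); consumes RNG.
# substitutions are drawn site-wise by inverse-CDF lookup in the cached
# cumulative transition kernel
sim_branch <- function(st, t, model, indels, scale, base_rate, getP) {
  L <- length(st$aa)
  if (L == 0L || t <= 0) return(st)
  teff <- t * scale
  for (u in unique(st$rate)) {
    cum <- getP(u * teff)$cum
    idx <- which(st$rate == u)
    uu <- stats::runif(length(idx))
    st$aa[idx] <- rowSums(cum[st$aa[idx], , drop = FALSE] < uu) + 1L
  }
  if (is.null(indels)) return(st)
  n_ins <- stats::rpois(1L, indels$lambda_ins * L * teff)
  n_del <- stats::rpois(1L, indels$lambda_del * L * teff)
  events <- sample(rep(c("I", "D"), c(n_ins, n_del)))
  for (ev in events) {
    L <- length(st$aa)
    if (ev == "I") {
      len <- zipf_lengths(indels, 1L)
      at <- sample.int(L + 1L, 1L) - 1L          # insert after position `at`
      ins_aa <- sample.int(20L, len, replace = TRUE, prob = model$pi)
      st$aa <- append(st$aa, ins_aa, after = at)
      st$rate <- append(st$rate, rep(base_rate, len), after = at)
      st$mask <- append(st$mask, rep(FALSE, len), after = at)
      st$hom <- append(st$hom, rep(NA_integer_, len), after = at)
    } else {
      if (L == 0L) next
      len <- zipf_lengths(indels, 1L)
      start <- sample.int(L, 1L)
      w <- start:min(L, start + len - 1L)
      if (any(st$mask[w])) {
        first <- which(st$mask[w])[1L]
        if (first == 1L) next                    # anchored on a masked residue
        w <- w[seq_len(first - 1L)]              # truncate to unmasked flank
      }
      st$aa <- st$aa[-w]; st$rate <- st$rate[-w]
      st$mask <- st$mask[-w]; st$hom <- st$hom[-w]
    }
  }
  st
}

root_state <- function(root, rates, mask) {
  L0 <- nchar(root)
  if (length(rates) == 1L) rates <- rep(as.numeric(rates), L0)
  if (length(rates) != L0) stop("rates must be scalar or length of root")
  if (is.null(mask)) mask <- rep(FALSE, L0)
  if (length(mask) != L0) stop("mask must have length of root")
  list(aa = encode_seq(root), rate = rates, mask = mask, hom = seq_len(L0))
}

#' Simulate evolution of one sequence along a phylogeny
#'
#' Along each branch of length `t` (multiplied by `scale` and the per-site
#' rate), substitutions are drawn site-wise from the exact transition kernel
#' `P(r_i * scale * t)`; insertion and deletion events are Poisson with mean
#' `lambda * L * scale * t`, with Zipf-distributed lengths and inserted
#' residues drawn from the model's stationary frequencies. Masked (conserved)
#' positions substitute at their own slow rate and are never deleted:
#' deletions overlapping the mask are truncated to the unmasked flank.
#' Descendants of one internal node share that node's simulated state
#' (proper recursive simulation). A sequence may shrink to length zero; the
#' corresponding leaves are returned as empty strings (a legal outcome
#' counted by [simulate_ensemble()]).
#'
#' @param root ungapped root amino-acid sequence.
#' @param tree `ape::phylo` tree with branch lengths in substitutions/site.
#' @param model a `subst_model`.
#' @param rates scalar rate multiplier, or per-root-site vector (e.g. column
#'   rates from [column_rates()] mapped to the region).
#' @param indels an `indel_model`, or `NULL` for substitution-only evolution.
#' @param scale evolutionary distance scaling factor (see
#'   [calibrate_scaling()]).
#' @param mask optional logical vector (length of `root`): conserved
#'   positions protected from deletion.
#' @param seed mandatory integer seed.
#' @return named character vector, one ungapped sequence per tip. Attribute
#'   `"homology"` holds, per tip, the 1-based root position of each residue
#'   (`NA` for inserted residues).
#' @export
evolve_sequence <- function(root, tree, model = default_subst_model(),
                            rates = 1, indels = indel_model(), scale = 1,
                            mask = NULL, seed) {
  validate_seq(root)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  st0 <- root_state(root, rates, mask)
  base_rate <- stats::median(st0$rate[!st0$mask])
  if (!is.finite(base_rate)) base_rate <- 1
  getP <- make_p_cache(model)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  rootnode <- ntip + 1L
  states <- vector("list", max(tree$edge))
  states[[rootnode]] <- st0
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    states[[child]] <- sim_branch(states[[parent]], tree$edge.length[e],
                                  model, indels, scale, base_rate, getP)
  }
  leaves <- vapply(seq_len(ntip),
                   function(i) decode_seq(states[[i]]$aa), character(1L))
  names(leaves) <- tree$tip.label
  attr(leaves, "homology") <- lapply(seq_len(ntip),
                                     function(i) states[[i]]$hom)
  leaves
}

#' Simulate an ensemble of null ortholog sets for one IDR
#'
#' Each replicate uses an independent seed derived deterministically from
#' `(seed, replicate index)`, so the ensemble is reproducible given
#' `(seed, n)` and replicate `i` alone is reproducible without simulating
#' `1..i-1`.
#'
#' @inheritParams evolve_sequence
#' @param n number of replicates (default 1000).
#' @param idr_id identifier carried through to downstream summaries.
#' @return object of class `sim_ensemble`: `replicates` (list of named
#'   character vectors), `n_nonempty` (replicates in which every species'
#'   sequence is non-empty), `idr_id`.
#' @export
simulate_ensemble <- function(root, tree, model = default_subst_model(),
                              rates = 1, indels = indel_model(), scale = 1,
                              mask = NULL, n = 1000L, seed,
                              idr_id = "idr") {
  if (missing(seed)) stop("seed is mandatory")
  reps <- vector("list", n)
  for (i in seq_len(n))
    reps[[i]] <- evolve_sequence(root, tree, model, rates, indels, scale,
                                 mask, seed = derive_seed(seed, i))
  nonempty <- vapply(reps, function(r) all(nchar(r) > 0L), logical(1L))
  structure(list(idr_id = idr_id, replicates = reps,
                 n_nonempty = sum(nonempty), nonempty = nonempty),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> %s: %d replicates, %d fully non-empty\n",
              x$idr_id, length(x$replicates), x$n_nonempty))
  invisible(x)
}

#' Reject ensembles with too many deleted (empty) simulations
#'
#' Accepted ensembles keep only their fully non-empty replicates for
#' downstream summaries; rejection is a return state, not an error.
#'
#' @param ensemble a `sim_ensemble`.
#' @param min_nonempty minimum fully non-empty replicates (default 950 of
#'   1000).
#' @return the filtered ensemble, or an `idr_rejected` object.
#' @export
filter_ensemble <- function(ensemble, min_nonempty = 950L) {
  if (ensemble$n_nonempty < min_nonempty)
    return(rejected(ensemble$idr_id, sprintf(
      "only %d non-empty simulations (need %d)",
      ensemble$n_nonempty, min_nonempty)))
  out <- ensemble
  out$replicates <- ensemble$replicates[ensemble$nonempty]
  out$nonempty <- rep(TRUE, length(out$replicates))
  out
}

#' Calibrate the evolutionary distance scaling factor
#'
#' The simulator consumes branch lengths in substitutions/site multiplied by
#' a global scale `s`, chosen so that the mean patristic distance between two
#' designated calibration taxa over all region trees equals 1 exactly.
#'
#' @param trees list of `ape::phylo` trees (or a `multiPhylo`).
#' @param taxonA,taxonB calibration taxon labels.
#' @return object of class `calibration_result`: `scale`, `pre_mean`,
#'   `post_mean` (`= scale * pre_mean = 1`), `n_used`, `n_skipped`.
#' @export
calibrate_scaling <- function(trees, taxonA, taxonB) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  d <- numeric(0); skipped <- 0L
  for (tr in trees) {
    if (!all(c(taxonA, taxonB) %in% tr$tip.label)) {
      skipped <- skipped + 1L
      next
    }
    dm <- ape::cophenetic.phylo(tr)
    d <- c(d, dm[taxonA, taxonB])
  }
  if (length(d) == 0L)
    stop("no tree contains both calibration taxa '", taxonA, "' and '",
         taxonB, "'")
  pre <- mean(d)
  if (pre <= 0) stop("calibration distance is zero; cannot scale")
  structure(list(scale = 1 / pre, pre_mean = pre, post_mean = (1 / pre) * pre,
                 n_used = length(d), n_skipped = skipped),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration> scale %.6g (pre-mean %.6g, post-mean %.6g, %d trees, %d skipped)\n",
    x$scale, x$pre_mean, x$post_mean, x$n_used, x$n_skipped))
  invisible(x)
}
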