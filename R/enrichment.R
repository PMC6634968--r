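# Annotation enrichment per cluster: hypergeometric tests against the
# clustering background, Benjamini-Hochberg correction, and the two
# permutation controls (uniform and composition-matched) with the
# sum-of-top-ten -log10 Q statistic.

#' Map IDR cluster membership to protein sets
#'
#' Annotations attach to proteins, not IDRs; proteins are deduplicated
#' within a cluster, and a protein with IDRs in several clusters appears in
#' each of them.
#'
#' @param assignment named cluster labels per IDR (NA = unassigned).
#' @param idr2prot named character vector mapping IDR id to protein id.
#' @return list: cluster label -> unique protein vector.
#' @export
map_idrs_to_proteins <- function(assignment, idr2prot) {
  labs <- sort(unique(assignment[!is.na(assignment)]))
  out <- lapply(labs, function(lab) {
    idrs <- names(assignment)[!is.na(assignment) & assignment == lab]
    unique(unname(idr2prot[idrs]))
  })
  stats::setNames(out, labs)
}

#' Drop overly generic annotation terms
#'
#' GO terms annotating more than `max_genes` proteins are removed;
#' phenotype/literature classes are kept unless listed in `classes`.
#'
#' @param tab an `annotation_table`.
#' @param max_genes maximum term size retained (default 5000).
#' @param classes term classes the filter applies to (default `"GO"`).
#' @return the filtered `annotation_table`.
#' @export
filter_terms <- function(tab, max_genes = 5000L, classes = "GO") {
  sz <- term_sizes(tab)
  too_big <- names(sz)[sz > max_genes]
  drop <- tab$term_id %in% too_big & tab$term_class %in% classes
  annotation_table(as.data.frame(tab[!drop, , drop = FALSE]))
}

#' Upper-tail hypergeometric enrichment test
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, n, K)`: drawing `K` cluster
#' proteins from a background of `N` containing `n` term-positive proteins.
#'
#' @param k term-positive proteins in the cluster.
#' @param K cluster size (proteins).
#' @param n term-positive proteins in the background.
#' @param N background size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; returned in input
#' order (ties keep input order).
#'
#' @param pvals p-value vector (NA allowed, passed through).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  m <- sum(!is.na(pvals))
  q <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  if (m == 0L) return(q)
  o <- ok[order(pvals[ok])]
  adj <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[o] <- pmin(adj, 1)
  q
}

#' Hypergeometric annotation enrichment for every cluster
#'
#' Background = all proteins contributing at least one IDR to the clustering
#' (union of the cluster protein sets plus, optionally, unassigned items'
#' proteins). BH correction is applied within each cluster by default;
#' `correction = "global"` pools all clusters.
#'
#' @param cluster_proteins list from [map_idrs_to_proteins()].
#' @param annotations an `annotation_table` (already through
#'   [filter_terms()] if desired).
#' @param background character vector of background proteins; defaults to
#'   the union of the cluster protein sets.
#' @param fdr retention threshold on q (default 0.05).
#' @param correction `"per_cluster"` (default) or `"global"`.
#' @param full if TRUE, report all tested terms, not only `q < fdr`.
#' @return data.frame: cluster, term_id, term_class, k, K, n, N, p, q.
#' @export
enrich_clusters <- function(cluster_proteins, annotations,
                            background = NULL, fdr = 0.05,
                            correction = c("per_cluster", "global"),
                            full = FALSE) {
  correction <- match.arg(correction)
  if (is.null(background))
    background <- unique(unlist(cluster_proteins, use.names = FALSE))
  N <- length(background)
  ann <- annotations[annotations$protein_id %in% background, , drop = FALSE]
  term_prot <- split(ann$protein_id, ann$term_id)
  term_class <- tapply(ann$term_class, ann$term_id, `[`, 1L)
  rows <- list()
  for (lab in names(cluster_proteins)) {
    prot <- intersect(cluster_proteins[[lab]], background)
    K <- length(prot)
    if (K == 0L || length(term_prot) == 0L) next
    k <- vapply(term_prot, function(tp) length(intersect(tp, prot)),
                integer(1L))
    n <- lengths(term_prot)
    p <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    rows[[lab]] <- data.frame(cluster = lab, term_id = names(term_prot),
                              term_class = unname(term_class[names(term_prot)]),
                              k = unname(k), K = K, n = unname(n), N = N,
                              p = unname(p), row.names = NULL)
  }
  if (length(rows) == 0L)
    return(data.frame(cluster = character(), term_id = character(),
                      term_class = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  res <- do.call(rbind, rows)
  res$q <- if (correction == "global") bh_fdr(res$p) else
    stats::ave(res$p, res$cluster, FUN = bh_fdr)
  rownames(res) <- NULL
  if (!full) res <- res[res$q < fdr, , drop = FALSE]
  res
}

# sum of the ten largest -log10 q (fewer pad with 0); q floored at eps
top_ten_stat <- function(qvals, n_top = 10L) {
  if (length(qvals) == 0L) return(0)
  v <- -log10(pmax(qvals, .Machine$double.eps))
  v <- sort(v, decreasing = TRUE)
  sum(v[seq_len(min(n_top, length(v)))])
}

#' Permutation control for cluster annotation enrichment
#'
#' The observed statistic is the sum of the ten largest `-log10 q` over the
#' cluster's enrichment tests. For each of `n_perm` permutations a
#' pseudo-cluster of the same size is drawn — uniformly from all clustered
#' IDRs, or composition-matched (each member replaced by a uniform draw from
#' its cell in the amino-acid-composition k-means clustering) — and the full
#' enrichment pipeline is re-run on it. `Z = (T_obs - mean(T_perm)) /
#' sd(T_perm)`.
#'
#' @param cluster_idrs IDR ids forming the cluster under test.
#' @param all_idrs all clustered IDR ids (the sampling frame).
#' @param idr2prot named IDR -> protein map.
#' @param annotations an `annotation_table`.
#' @param sampler `"uniform"` or `"composition_matched"`.
#' @param comp_assignment named composition-cell labels per IDR (required
#'   for the composition-matched sampler).
#' @param n_perm number of permutations (default 1000).
#' @param fdr q computation threshold context (statistic uses all q-values;
#'   `fdr` only matters for reported term lists elsewhere).
#' @param seed integer seed.
#' @return list: `T_obs`, `null_mean`, `null_sd`, `Z` (NA with a warning if
#'   the null sd is 0), `n_perm`.
#' @export
permutation_z <- function(cluster_idrs, all_idrs, idr2prot, annotations,
                          sampler = c("uniform", "composition_matched"),
                          comp_assignment = NULL, n_perm = 1000L,
                          fdr = 0.05, seed = 1L) {
  sampler <- match.arg(sampler)
  if (sampler == "composition_matched" && is.null(comp_assignment))
    stop("composition_matched sampler needs comp_assignment")
  background <- unique(unname(idr2prot[all_idrs]))
  stat_for <- function(idrs) {
    prot <- list(X = unique(unname(idr2prot[idrs])))
    res <- enrich_clusters(prot, annotations, background = background,
                           full = TRUE)
    top_ten_stat(res$q)
  }
  T_obs <- stat_for(cluster_idrs)
  m <- length(cluster_idrs)
  set.seed(seed)
  if (sampler == "composition_matched") {
    cells <- split(all_idrs, comp_assignment[all_idrs])
    member_cell <- comp_assignment[cluster_idrs]
  }
  T_perm <- vapply(seq_len(n_perm), function(b) {
    idrs <- if (sampler == "uniform") sample(all_idrs, m) else
      vapply(member_cell, function(cl) {
        pool <- cells[[as.character(cl)]]
        pool[sample.int(length(pool), 1L)]
      }, character(1L))
    stat_for(idrs)
  }, numeric(1L))
  mu <- mean(T_perm); s <- stats::sd(T_perm)
  if (is.na(s) || s == 0) {
    warning("permutation null has zero spread; Z is MISSING")
    z <- NA_real_
  } else z <- (T_obs - mu) / s
  list(T_obs = T_obs, null_mean = mu, null_sd = s, Z = z, n_perm = n_perm)
}
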