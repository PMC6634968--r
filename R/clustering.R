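# Clustering of evolutionary signatures: weighted uncentered correlation
# distance, UPGMA (average linkage) with deterministic tie-breaking, tree
# cutting with a minimum cluster size, the amino-acid-composition k-means
# control, the pairwise sequence-similarity control, and annotation transfer
# to query IDRs.

#' Uncentered correlation distance between two vectors
#'
#' `r = sum(w x y) / sqrt(sum(w x^2) sum(w y^2))` over pairwise-complete
#' dimensions (no mean-centering), `d = 1 - r`, so `d` lies in `[0, 2]`.
#'
#' @param x,y numeric vectors (NA allowed).
#' @param w optional non-negative dimension weights.
#' @return distance in `[0, 2]`.
#' @export
uncentered_correlation_distance <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no pairwise-complete dimensions")
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  nx <- sum(w * x^2); ny <- sum(w * y^2)
  if (nx <= 0 || ny <= 0) stop("zero norm in uncentered correlation")
  1 - sum(w * x * y) / sqrt(nx * ny)
}

#' All-pairs uncentered correlation distances for a signature matrix
#'
#' Pairs sharing fewer than `min_shared` of the dimensions get a MISSING
#' distance, which is then imputed as the matrix maximum (count reported in
#' attribute `"n_imputed"`).
#'
#' @param zmat item x dimension matrix (NA allowed).
#' @param w optional dimension weights.
#' @param min_shared minimum shared fraction of dimensions (default 0.5).
#' @return symmetric distance matrix with zero diagonal.
#' @export
signature_distances <- function(zmat, w = NULL, min_shared = 0.5) {
  n <- nrow(zmat)
  d <- matrix(0, n, n, dimnames = list(rownames(zmat), rownames(zmat)))
  nd <- ncol(zmat)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- mean(!is.na(zmat[i, ]) & !is.na(zmat[j, ]))
    d[i, j] <- d[j, i] <- if (shared < min_shared) NA_real_ else
      uncentered_correlation_distance(zmat[i, ], zmat[j, ], w)
  }
  n_imp <- sum(is.na(d)) / 2L
  if (n_imp > 0L) d[is.na(d)] <- max(d, na.rm = TRUE)
  attr(d, "n_imputed") <- n_imp
  d
}

#' Density-based item weights (Cluster 3.0 style)
#'
#' `w_i = 1 / sum_j max(0, 1 - d(i,j)/cutoff)^exponent` with the self term
#' included, so items in dense neighbourhoods are down-weighted and isolated
#' items get weight 1.
#'
#' @param d symmetric distance matrix.
#' @param cutoff neighbourhood radius (default 0.8).
#' @param exponent contribution exponent (default 1).
#' @return positive weight per item.
#' @export
compute_item_weights <- function(d, cutoff = 0.8, exponent = 1) {
  contrib <- pmax(1 - d / cutoff, 0)^exponent   # arg order keeps dim
  1 / rowSums(contrib)
}

#' UPGMA (average linkage) hierarchical clustering
#'
#' Deterministic merge order: at each step the pair with the smallest
#' average inter-cluster distance merges; exact ties are broken by the
#' smallest `(i, j)` index pair. Returns a standard `hclust` object so
#' `stats::cutree()` and plotting work.
#'
#' @param d symmetric distance matrix with labels.
#' @return an `hclust` object (method `"average"`).
#' @export
average_linkage <- function(d) {
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)
  id <- -seq_len(n)            # hclust convention: negatives are leaves
  size <- rep(1L, n)
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    bi <- bj <- 1L; bd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- dm[i, j]
      if (dij < bd) { bd <- dij; bi <- i; bj <- j }
    }
    merge[step, ] <- sort(c(id[bi], id[bj]))
    height[step] <- bd
    # Lance-Williams average-linkage update
    newrow <- (size[bi] * dm[bi, ] + size[bj] * dm[bj, ]) /
      (size[bi] + size[bj])
    keep <- setdiff(seq_len(m), c(bi, bj))
    dm <- dm[keep, keep, drop = FALSE]
    nr <- newrow[keep]
    dm <- rbind(cbind(dm, nr), c(nr, 0))
    size <- c(size[keep], size[bi] + size[bj])
    id <- c(id[keep], step)
    active <- c(active[keep], 0L)
  }
  order <- dendro_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 dist.method = "uncentered"),
            class = "hclust")
}

dendro_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Cut a dendrogram into clusters with a minimum size
#'
#' Subtrees below the cut with at least `min_size` members become clusters;
#' smaller groups are left unassigned (they stay in the enrichment
#' background but form no cluster). A programmatic surrogate for manual
#' cluster picking.
#'
#' @param dend `hclust` object from [average_linkage()].
#' @param height cut height (or use `k`).
#' @param k number of groups (used when `height` is NULL).
#' @param min_size minimum cluster size (default 15).
#' @return list: `assignment` (named vector, NA = unassigned), `clusters`
#'   (label -> member vector).
#' @export
cut_clusters <- function(dend, height = NULL, k = NULL, min_size = 15L) {
  groups <- if (!is.null(height)) stats::cutree(dend, h = height)
            else stats::cutree(dend, k = k)
  tab <- table(groups)
  big <- names(tab)[tab >= min_size]
  assignment <- rep(NA_character_, length(groups))
  names(assignment) <- names(groups)
  for (i in seq_along(big))
    assignment[groups == as.integer(big[i])] <- paste0("C", i)
  clusters <- split(names(assignment)[!is.na(assignment)],
                    assignment[!is.na(assignment)])
  list(assignment = assignment, clusters = clusters)
}

#' Amino-acid frequency Z-score vectors
#'
#' Per-IDR 20-dimensional composition normalized to the "proteome" average:
#' `z_i = (freq_i - mean_i) / sd_i` with mean and sd taken over the supplied
#' sequence collection (or supplied explicitly).
#'
#' @param seqs named character vector of ungapped sequences.
#' @param center,scale optional proteome-wide per-residue mean and sd.
#' @return item x 20 matrix of composition Z-scores.
#' @export
aa_freq_zscores <- function(seqs, center = NULL, scale = NULL) {
  freq <- t(vapply(seqs, function(s) {
    n <- aa_counts(aa_chars(s)); n / sum(n)
  }, numeric(20L)))
  if (is.null(center)) center <- colMeans(freq)
  if (is.null(scale)) scale <- apply(freq, 2L, stats::sd)
  scale[scale == 0] <- 1
  sweep(sweep(freq, 2L, center), 2L, scale, "/")
}

#' K-means clustering of composition Z-scores
#'
#' @param aa_freq_z matrix from [aa_freq_zscores()].
#' @param K number of clusters (default 25); if `K >= nrow`, every item
#'   becomes its own cluster.
#' @param seed integer seed (reproducibility contract).
#' @param nstart,iter.max passed to [stats::kmeans()].
#' @return list: `assignment` (named integer vector), `centers`, `tot_withinss`.
#' @export
composition_kmeans <- function(aa_freq_z, K = 25L, seed = 1L,
                               nstart = 5L, iter.max = 50L) {
  n <- nrow(aa_freq_z)
  if (K >= n) {
    assignment <- stats::setNames(seq_len(n), rownames(aa_freq_z))
    return(list(assignment = assignment, centers = aa_freq_z,
                tot_withinss = 0))
  }
  set.seed(seed)
  km <- stats::kmeans(aa_freq_z, centers = K, nstart = nstart,
                      iter.max = iter.max)
  list(assignment = stats::setNames(km$cluster, rownames(aa_freq_z)),
       centers = km$centers, tot_withinss = km$tot.withinss)
}

#' Pairwise alignment dissimilarity (BLOSUM62 global alignment)
#'
#' Global (Needleman-Wunsch) alignment with gap opening 0 and gap extension
#' 1 under BLOSUM62; the score is transformed to a dissimilarity
#' `d = 1 - S(a,b) / min(S(a,a), S(b,b))`, so identical sequences get 0.
#'
#' @param seqs named character vector of ungapped sequences.
#' @return symmetric dissimilarity matrix.
#' @export
alignment_distances <- function(seqs) {
  n <- length(seqs)
  aa <- Biostrings::AAStringSet(seqs)
  self <- vapply(seq_len(n), function(i)
    Biostrings::pairwiseAlignment(aa[i], aa[i],
                                  substitutionMatrix = "BLOSUM62",
                                  gapOpening = 0, gapExtension = 1,
                                  scoreOnly = TRUE), numeric(1L))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    sc <- Biostrings::pairwiseAlignment(aa[(i + 1L):n], aa[i],
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 0, gapExtension = 1,
                                        scoreOnly = TRUE)
    dij <- 1 - sc / pmin(self[(i + 1L):n], self[i])
    d[i, (i + 1L):n] <- dij
    d[(i + 1L):n, i] <- dij
  }
  d
}

#' Sequence-similarity control for a clustering
#'
#' Tests whether clusters could be explained by raw sequence similarity: the
#' 1st percentile of all pairwise alignment dissimilarities defines "highly
#' similar"; a member counts if it has a within-cluster partner at or below
#' that threshold. Reported per cluster as a percentage (singleton clusters
#' give 0).
#'
#' @param assignment named cluster labels (NA = unassigned).
#' @param seqs named ungapped sequences for the same items.
#' @param top_fraction similarity quantile (default 0.01).
#' @return named numeric: percent of flagged members per cluster.
#' @export
similarity_control <- function(assignment, seqs, top_fraction = 0.01) {
  seqs <- seqs[names(assignment)]
  d <- alignment_distances(seqs)
  thr <- stats::quantile(d[upper.tri(d)], top_fraction, names = FALSE)
  labs <- sort(unique(assignment[!is.na(assignment)]))
  out <- stats::setNames(numeric(length(labs)), labs)
  for (lab in labs) {
    members <- names(assignment)[!is.na(assignment) & assignment == lab]
    if (length(members) < 2L) { out[lab] <- 0; next }
    sub <- d[members, members]
    diag(sub) <- Inf
    out[lab] <- 100 * mean(apply(sub, 1L, min) <= thr)
  }
  out
}

#' Transfer cluster annotations to a query signature
#'
#' The query is compared with each cluster's centroid (column means over
#' members, missing cells ignored) under uncentered correlation distance;
#' the nearest cluster's enriched annotations are transferred, with the
#' distance and the margin to the runner-up reported. A margin below
#' `ambiguity_margin` flags the call as ambiguous.
#'
#' @param query named Z-score vector (2F).
#' @param zmat signature matrix of the clustered IDRs.
#' @param assignment named cluster labels for `zmat` rows.
#' @param cluster_annotations optional list label -> annotation terms
#'   (e.g. significant terms from [enrich_clusters()]).
#' @param ambiguity_margin minimum margin for an unambiguous call.
#' @return list: `ranking` (data.frame label/distance), `cluster`, `margin`,
#'   `ambiguous`, `terms`.
#' @export
annotate_query <- function(query, zmat, assignment,
                           cluster_annotations = NULL,
                           ambiguity_margin = 1e-6) {
  labs <- sort(unique(assignment[!is.na(assignment)]))
  dist <- vapply(labs, function(lab) {
    members <- names(assignment)[!is.na(assignment) & assignment == lab]
    centroid <- colMeans(zmat[members, , drop = FALSE], na.rm = TRUE)
    uncentered_correlation_distance(query, centroid)
  }, numeric(1L))
  ord <- order(dist)
  margin <- if (length(dist) > 1L) dist[ord[2L]] - dist[ord[1L]] else Inf
  best <- labs[ord[1L]]
  list(ranking = data.frame(cluster = labs[ord], distance = dist[ord],
                            row.names = NULL),
       cluster = best, distance = dist[ord[1L]], margin = margin,
       ambiguous = margin < ambiguity_margin,
       terms = if (!is.null(cluster_annotations))
         cluster_annotations[[best]] else NULL)
}
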