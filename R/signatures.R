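# Evolutionary signatures: across-ortholog feature summaries (mean and
# log-variance), empirical p-values and Z-scores of the real ortholog set
# against its simulated null ensemble, significance counting, and the
# signature filters applied before clustering.

#' Across-ortholog summary of one feature
#'
#' @param values per-ortholog feature values (NA = undefined for that
#'   ortholog).
#' @return list with `mean`, `log_variance` (natural log of the unbiased
#'   sample variance; NA when the variance is 0), `n_used`. Both statistics
#'   are NA with fewer than 2 defined values.
#' @export
summarize <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L)
    return(list(mean = NA_real_, log_variance = NA_real_,
                n_used = length(v)))
  s2 <- stats::var(v)
  list(mean = mean(v),
       log_variance = if (s2 > 0) log(s2) else NA_real_,
       n_used = length(v))
}

#' Feature summaries (mean + log-variance blocks) for one ortholog set
#'
#' @param seqs ungapped ortholog sequences (empty strings skipped).
#' @param catalog a `feature_catalog`.
#' @return named numeric vector of length 2F: `mean_<feature>` block in
#'   catalog order, then `logvar_<feature>` block.
#' @export
summarize_set <- function(seqs, catalog = default_catalog()) {
  seqs <- seqs[nchar(seqs) > 0L]
  fm <- feature_matrix(seqs, catalog)
  nm <- catalog_names(catalog)
  nobs <- colSums(!is.na(fm))
  mu <- colMeans(fm, na.rm = TRUE)
  v <- colSums(sweep(fm, 2L, mu)^2, na.rm = TRUE) / pmax(nobs - 1L, 1L)
  means <- ifelse(nobs >= 2L, mu, NA_real_)
  lvars <- ifelse(nobs >= 2L & v > 0, log(v), NA_real_)
  stats::setNames(c(means, lvars),
                  c(paste0("mean_", nm), paste0("logvar_", nm)))
}

#' Summary matrix over a simulated ensemble
#'
#' @param ensemble a `sim_ensemble` (typically after [filter_ensemble()]).
#' @param catalog a `feature_catalog`.
#' @return matrix (replicates x 2F) of per-replicate summaries.
#' @export
ensemble_summaries <- function(ensemble, catalog = default_catalog()) {
  t(vapply(ensemble$replicates, summarize_set,
           numeric(2L * length(catalog)), catalog = catalog))
}

#' Two-tailed empirical p-value with add-one pseudocount
#'
#' `p_hi = (1 + #\{null >= obs\}) / (n + 1)`, `p_lo` analogously, and
#' `p = min(1, 2 min(p_hi, p_lo))`. The pseudocount guarantees `p > 0` and
#' makes the floor at `n` replicates explicit (`2/(n+1)`).
#'
#' @param obs observed value.
#' @param null vector of null replicate values (NAs dropped).
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(obs, null) {
  null <- null[!is.na(null)]
  n <- length(null)
  if (n == 0L) stop("empty null distribution")
  if (is.na(obs)) return(NA_real_)
  p_hi <- (1 + sum(null >= obs)) / (n + 1)
  p_lo <- (1 + sum(null <= obs)) / (n + 1)
  min(1, 2 * min(p_hi, p_lo))
}

#' Z-score of an observed value against the simulation null
#'
#' `Z = (x - mu) / sigma` with `mu`, `sigma` the mean and standard deviation
#' of the simulated values.
#'
#' @param x observed value.
#' @param mu,sigma null mean and standard deviation.
#' @return Z, or NA when `sigma` is 0 or missing.
#' @export
zscore <- function(x, mu, sigma) {
  if (is.na(x) || is.na(mu) || is.na(sigma) || sigma <= 0) return(NA_real_)
  (x - mu) / sigma
}

#' Build the evolutionary signature of one IDR
#'
#' For each feature x statistic (mean, log-variance), the observed summary is
#' compared with the distribution over the null ensemble: an empirical
#' p-value (two-tailed, add-one) and a Z-score. Cells where the observed
#' summary, the null mean, or the null standard deviation is undefined are
#' MISSING and reduce `presence`.
#'
#' @param real named 2F summary vector from [summarize_set()].
#' @param null_mat replicate x 2F matrix from [ensemble_summaries()].
#' @param alpha significance level for the per-cell flags (default 0.01).
#' @return list: `z` (named 2F vector), `p` (named 2F vector), `presence`
#'   (fraction of non-missing Z cells), `significant` (logical per cell),
#'   `n_replicates`.
#' @export
build_signature <- function(real, null_mat, alpha = 0.01) {
  stopifnot(identical(names(real), colnames(null_mat)))
  k <- length(real)
  z <- p <- rep(NA_real_, k)
  names(z) <- names(p) <- names(real)
  for (j in seq_len(k)) {
    nullv <- null_mat[, j]
    nullv <- nullv[!is.na(nullv)]
    if (length(nullv) < 2L || is.na(real[j])) next
    z[j] <- zscore(real[j], mean(nullv), stats::sd(nullv))
    p[j] <- empirical_pvalue(real[j], nullv)
  }
  list(z = z, p = p, presence = mean(!is.na(z)),
       significant = !is.na(p) & p < alpha,
       n_replicates = nrow(null_mat))
}

#' Number of features significant in mean, log-variance, or both
#'
#' A feature counts once if either its mean or its log-variance deviates
#' from the null at the chosen level.
#'
#' @param sig result of [build_signature()] (or a logical/named p vector
#'   over the 2F cells).
#' @param alpha significance level (default 0.01).
#' @return integer count of significant features.
#' @export
count_significant <- function(sig, alpha = 0.01) {
  p <- if (is.list(sig)) sig$p else sig
  k <- length(p) %/% 2L
  hit <- !is.na(p) & p < alpha
  sum(hit[seq_len(k)] | hit[k + seq_len(k)])
}

#' Chance expectation for the significant-feature count
#'
#' For each ensemble, one replicate is chosen uniformly at random, treated as
#' the "real" ortholog set, and scored against the remaining replicates
#' (leave-one-out, so the chosen replicate never sits in its own null). The
#' distribution of significant-feature counts over IDRs is the chance
#' expectation for the real-data counts.
#'
#' @param summaries list of replicate x 2F summary matrices (one per
#'   ensemble), or list of `sim_ensemble` objects (summaries then computed
#'   with `catalog`).
#' @param catalog used only when ensembles are passed.
#' @param alpha significance level (default 0.01).
#' @param seed integer seed for the replicate choices.
#' @return integer vector: per-IDR significant-feature counts.
#' @export
chance_expectation <- function(summaries, catalog = default_catalog(),
                               alpha = 0.01, seed = 1L) {
  set.seed(seed)
  vapply(summaries, function(sm) {
    if (inherits(sm, "sim_ensemble")) sm <- ensemble_summaries(sm, catalog)
    j <- sample.int(nrow(sm), 1L)
    sig <- build_signature(sm[j, ], sm[-j, , drop = FALSE], alpha)
    count_significant(sig, alpha)
  }, integer(1L))
}

#' Filter signatures before clustering
#'
#' Keeps signatures with at least one `|Z| >= min_abs_z` and at least
#' `min_presence` of the 2F cells defined.
#'
#' @param zmat IDR x 2F Z-score matrix (NA = missing cell).
#' @param min_abs_z minimum absolute Z (default 3).
#' @param min_presence minimum fraction of defined cells (default 0.95).
#' @return the filtered matrix (possibly 0 rows).
#' @export
filter_signatures <- function(zmat, min_abs_z = 3, min_presence = 0.95) {
  maxabs <- apply(zmat, 1L, function(r)
    if (all(is.na(r))) -Inf else max(abs(r), na.rm = TRUE))
  presence <- rowMeans(!is.na(zmat))
  zmat[maxabs >= min_abs_z & presence >= min_presence, , drop = FALSE]
}
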