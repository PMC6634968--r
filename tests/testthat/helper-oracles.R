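# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as plain loops, independent of the
# package's implementation paths.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n, seed = NULL, pool = AA) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), f)
  f
}

# brute-force SCD: explicit double loop over all position pairs
scd_brute <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  q <- numeric(length(ch))
  q[ch %in% c("K", "R")] <- 1
  q[ch %in% c("D", "E")] <- -1
  tot <- 0
  n <- length(ch)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    tot <- tot + q[i] * q[j] * sqrt(j - i)
  tot / n
}

# brute-force kappa: explicit window loops for delta; segregated arrangement
# built independently (positives, neutrals, negatives)
kappa_brute <- function(seq, blobs = c(5, 6)) {
  ch <- strsplit(seq, "")[[1]]
  pos <- ch %in% c("K", "R"); neg <- ch %in% c("D", "E")
  if (!any(pos | neg)) return(NA_real_)
  sigma <- function(fp, fm) if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
  delta <- function(p, m, g) {
    L <- length(p)
    glob <- sigma(mean(p), mean(m))
    devs <- numeric(0)
    for (i in seq_len(L - g + 1)) {
      w <- i:(i + g - 1)
      devs <- c(devs, (sigma(mean(p[w]), mean(m[w])) - glob)^2)
    }
    mean(devs)
  }
  L <- length(ch)
  segp <- c(rep(TRUE, sum(pos)), rep(FALSE, L - sum(pos)))
  segm <- c(rep(FALSE, L - sum(neg)), rep(TRUE, sum(neg)))
  vals <- numeric(0)
  for (g in blobs) {
    if (L < g) next
    dmax <- delta(segp, segm, g)
    if (dmax <= 0) next
    vals <- c(vals, delta(pos, neg, g) / dmax)
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# exact hypergeometric upper tail by term-by-term enumeration
hyper_brute <- function(k, K, n, N) {
  tot <- 0
  for (j in k:min(K, n))
    tot <- tot + choose(n, j) * choose(N - n, K - j)
  tot / choose(N, K)
}

# naive O(n^3) UPGMA: recompute average inter-group distance from scratch
upgma_brute <- function(d) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  gdist <- function(a, b) mean(d[a, b])
  while (length(groups) > 1) {
    m <- length(groups)
    bi <- bj <- 1; bd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dd <- gdist(groups[[i]], groups[[j]])
      if (dd < bd) { bd <- dd; bi <- i; bj <- j }
    }
    heights <- c(heights, bd)
    merges[[length(merges) + 1]] <- sort(c(length(groups[[bi]]) ,
                                           length(groups[[bj]])))
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  list(heights = heights, sizes = merges)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# small star-ish test trees written as Newick text
newick_tree <- function(txt) ape::read.tree(text = txt)
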