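# Reversible amino-acid substitution model (GTR-style construction) with an
# eigendecomposition-backed transition-probability kernel, plus the power-law
# indel model. Time units: expected substitutions per site.

#' Build a reversible substitution model
#'
#' Off-diagonal rates are `q_ab = s_ab * pi_b` from symmetric exchangeabilities
#' `s` and stationary frequencies `pi`; the diagonal makes rows sum to zero
#' and the matrix is normalized so the expected substitution rate at
#' stationarity, `-sum_a pi_a q_aa`, equals 1. The model is reversible
#' (`pi_a q_ab = pi_b q_ba`) by construction, so transition probabilities are
#' computed exactly via symmetric eigendecomposition.
#'
#' @param freqs named numeric of length 20 over ACDEFGHIKLMNPQRSTVWY, summing
#'   to 1 (tolerance 1e-9).
#' @param exch symmetric non-negative 20 x 20 exchangeability matrix with zero
#'   diagonal, or a single number for uniform exchangeabilities.
#' @return object of class `subst_model` with fields `pi`, `Q` and cached
#'   eigendecomposition.
#' @export
build_rate_matrix <- function(freqs, exch = 1) {
  if (length(freqs) != 20L) stop("freqs must have length 20")
  if (is.null(names(freqs))) names(freqs) <- AA20
  freqs <- freqs[AA20]
  if (any(is.na(freqs)) || any(freqs < 0)) stop("negative or missing frequencies")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (length(exch) == 1L) exch <- matrix(exch, 20L, 20L)
  if (!isTRUE(all.equal(exch, t(exch)))) stop("exchangeabilities must be symmetric")
  if (any(exch < 0)) stop("negative exchangeabilities")
  diag(exch) <- 0
  Q <- exch * rep(freqs, each = 20L)          # q_ab = s_ab * pi_b
  diag(Q) <- -rowSums(Q)
  norm <- -sum(freqs * diag(Q))
  if (norm <= 0) stop("degenerate model: zero total rate")
  Q <- Q / norm
  dimnames(Q) <- list(AA20, AA20)
  d <- sqrt(freqs)
  S <- Q * (d %o% (1 / d))                    # symmetric similarity transform
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  structure(list(pi = freqs, Q = Q,
                 V = eig$vectors / d,          # rows scaled by 1/sqrt(pi)
                 Vi = t(eig$vectors * d),      # columns scaled by sqrt(pi)
                 lambda = eig$values),
            class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a `subst_model`.
#' @param t evolutionary time (expected substitutions per site at rate 1).
#' @return 20 x 20 stochastic matrix.
#' @export
model_P <- function(model, t) {
  if (t < 0) stop("negative time")
  P <- model$V %*% (exp(model$lambda * t) * model$Vi)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> reversible 20-state model, rate-normalized;",
      "top frequencies:", paste(names(sort(x$pi, decreasing = TRUE))[1:5],
                                collapse = " "), "\n")
  invisible(x)
}

#' Default disorder-specific substitution model
#'
#' Stationary frequencies emulate the composition of budding-yeast predicted
#' disordered regions: enriched in S, N, Q, D, E, K, P, G, T and depleted in
#' the hydrophobic/aromatic residues that favour folding. These are
#' package-defined representative values (the composition is configurable —
#' see [estimate_stationary_freqs()] to derive one from your own disordered
#' sequences). Exchangeabilities default to uniform, a deliberately neutral
#' stand-in documented in the methods vignette.
#'
#' @return a `subst_model`.
#' @export
default_subst_model <- function() {
  freqs <- c(A = 0.070, C = 0.005, D = 0.060, E = 0.080, F = 0.020,
             G = 0.070, H = 0.020, I = 0.030, K = 0.080, L = 0.050,
             M = 0.015, N = 0.070, P = 0.070, Q = 0.060, R = 0.045,
             S = 0.130, T = 0.060, V = 0.040, W = 0.005, Y = 0.020)
  build_rate_matrix(freqs, 1)
}

#' Estimate stationary frequencies from a pool of sequences
#'
#' Pooled residue counts with a pseudocount of 1 per residue type, so the
#' result is strictly positive even for small pools.
#'
#' @param seqs character vector of ungapped sequences (may be empty).
#' @return named frequency vector over the 20 residues, summing to 1.
#' @export
estimate_stationary_freqs <- function(seqs) {
  n <- rep(0, 20L); names(n) <- AA20
  for (s in seqs) {
    if (nchar(s) == 0L) next
    n <- n + aa_counts(aa_chars(s))
  }
  n <- n + 1
  n / sum(n)
}

#' Power-law indel model
#'
#' Insertion and deletion events arrive as Poisson processes per residue per
#' unit time; event lengths follow a Zipf (discrete power-law) distribution
#' with exponent `alpha`, truncated at `L_max`; inserted residues are drawn
#' from the substitution model's stationary frequencies. The defaults
#' (0.03 events/residue/unit time, alpha 1.8, max length 50) are
#' package-declared stand-ins of the right order of magnitude for protein
#' indel surveys, not published constants.
#'
#' @param lambda_ins,lambda_del event rates per residue per unit time.
#' @param alpha power-law exponent (> 1).
#' @param L_max truncation length (>= 1).
#' @return object of class `indel_model`.
#' @export
indel_model <- function(lambda_ins = 0.03, lambda_del = 0.03,
                        alpha = 1.8, L_max = 50L) {
  if (lambda_ins < 0 || lambda_del < 0) stop("indel rates must be >= 0")
  if (alpha <= 1) stop("alpha must be > 1")
  if (L_max < 1L) stop("L_max must be >= 1")
  k <- seq_len(L_max)
  p <- k^(-alpha); p <- p / sum(p)
  structure(list(lambda_ins = lambda_ins, lambda_del = lambda_del,
                 alpha = alpha, L_max = as.integer(L_max), length_probs = p),
            class = "indel_model")
}

#' Truncated Zipf mass function / sampler for indel lengths
#'
#' @param m an `indel_model`.
#' @param n number of draws.
#' @return `zipf_lengths`: integer draws in `1..L_max`.
#' @export
zipf_lengths <- function(m, n) {
  sample.int(m$L_max, n, replace = TRUE, prob = m$length_probs)
}
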