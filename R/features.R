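# Molecular feature catalog and per-sequence feature computation.
# All features are computed on ungapped amino-acid sequences. Values that are
# undefined for a sequence's composition (e.g. charge patterning with no
# charged residues) are MISSING (NA), never 0.

POSITIVE <- c("K", "R")
NEGATIVE <- c("D", "E")
CHARGED <- c(POSITIVE, NEGATIVE)

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# EMBOSS pKa set; configurable via the `pka` argument of isoelectric_point()
EMBOSS_PKA <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
                D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

aa_chars <- function(seq) strsplit(seq, "")[[1L]]

validate_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("sequence must be a single non-empty string")
  if (grepl("-", seq, fixed = TRUE))
    stop("sequence contains gaps; features are defined on ungapped sequences")
  if (grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seq))
    stop("sequence contains characters outside the 20-letter alphabet")
  invisible(seq)
}

aa_counts <- function(ch) {
  idx <- match(ch, AA20)
  n <- tabulate(idx, nbins = 20L)
  names(n) <- AA20
  n
}

#' Fraction of residues belonging to a residue set
#' @param seq ungapped amino-acid string.
#' @param residues character vector of single-letter residues.
#' @return fraction in `[0, 1]`.
#' @export
aa_fraction <- function(seq, residues) {
  validate_seq(seq)
  ch <- aa_chars(seq)
  mean(ch %in% residues)
}

#' Net charge, optionally with phosphorylated positions
#'
#' +1 per K/R, -1 per D/E, `phospho_charge` per phosphosite; histidine
#' contributes 0.
#'
#' @param seq ungapped amino-acid string.
#' @param phospho_sites 0-based positions carrying a phosphate.
#' @param phospho_charge charge per phosphosite (default -2, fully ionized).
#' @return net charge (signed real).
#' @export
net_charge <- function(seq, phospho_sites = NULL, phospho_charge = -2) {
  validate_seq(seq)
  ch <- aa_chars(seq)
  sum(ch %in% POSITIVE) - sum(ch %in% NEGATIVE) +
    phospho_charge * length(phospho_sites)
}

scd_core <- function(ch) {
  q <- ifelse(ch %in% POSITIVE, 1, ifelse(ch %in% NEGATIVE, -1, 0))
  pos <- which(q != 0)
  if (length(pos) < 2L) return(0)
  qq <- q[pos]
  tot <- 0
  for (i in seq_len(length(pos) - 1L)) {
    j <- (i + 1L):length(pos)
    tot <- tot + sum(qq[i] * qq[j] * sqrt(pos[j] - pos[i]))
  }
  tot / length(ch)
}

#' Sequence charge decoration (SCD)
#'
#' Distance-weighted sum of pairwise charge products,
#' `(1/N) * sum_{i<j} q_i q_j sqrt(j - i)` with q = +1 for K/R, -1 for D/E.
#' Sensitive to charge blockiness: blocky sequences give large positive
#' values, well-mixed polyampholytes negative values near zero.
#'
#' @param seq ungapped amino-acid string.
#' @return SCD value (0 for sequences with fewer than two charges).
#' @export
scd <- function(seq) {
  validate_seq(seq)
  scd_core(aa_chars(seq))
}

# Blob asymmetry sigma = (fA - fB)^2 / (fA + fB); 0 where the blob has no
# group residues. fA/fB are per-blob fractions of the two residue groups.
blob_sigma <- function(fA, fB) {
  s <- fA + fB
  out <- numeric(length(fA))
  nz <- s > 0
  out[nz] <- (fA[nz] - fB[nz])^2 / s[nz]
  out
}

patterning_delta <- function(isA, isB, g) {
  L <- length(isA)
  csA <- c(0, cumsum(isA)); csB <- c(0, cumsum(isB))
  i <- seq_len(L - g + 1L)
  fA <- (csA[i + g] - csA[i]) / g
  fB <- (csB[i + g] - csB[i]) / g
  sig <- blob_sigma(fA, fB)
  glob <- blob_sigma(mean(isA), mean(isB))
  mean((sig - glob)^2)
}

#' Charge / proline patterning statistics (kappa, omega)
#'
#' Measures segregation versus mixing of two residue groups along the
#' sequence. For each blob size, per-blob group asymmetry is compared with
#' the global asymmetry; the mean squared deviation is normalized by its
#' value on the fully segregated arrangement of the same composition, so the
#' result lies in `[0, 1]` (1 = maximally segregated).
#'
#' `kappa` contrasts positive (K/R) vs negative (D/E) residues and requires
#' at least one charged residue; `omega` contrasts \{proline + charged\}
#' against everything else and requires at least one residue in that group.
#'
#' @param seq ungapped amino-acid string.
#' @param alphabet_split `"kappa"` or `"omega"`.
#' @param blob_sizes blob (window) sizes averaged over; default `c(5, 6)`.
#' @return value in `[0, 1]`, or `NA` when undefined (no group residues, all
#'   blob sizes longer than the sequence, or a composition whose segregated
#'   arrangement carries no patterning contrast).
#' @export
patterning <- function(seq, alphabet_split = c("kappa", "omega"),
                       blob_sizes = c(5L, 6L)) {
  validate_seq(seq)
  patterning_core(aa_chars(seq), match.arg(alphabet_split), blob_sizes)
}

patterning_core <- function(ch, alphabet_split, blob_sizes) {
  if (alphabet_split == "kappa") {
    isA <- as.numeric(ch %in% POSITIVE)
    isB <- as.numeric(ch %in% NEGATIVE)
    if (sum(isA) + sum(isB) == 0) return(NA_real_)
  } else {
    isA <- as.numeric(ch %in% c("P", CHARGED))
    isB <- 1 - isA
    if (sum(isA) == 0) return(NA_real_)
  }
  # fully segregated arrangement: A block, then neutral, then B block
  nA <- sum(isA); nB <- sum(isB); L <- length(ch)
  segA <- c(rep(1, nA), rep(0, L - nA))
  segB <- c(rep(0, L - nB), rep(1, nB))
  vals <- numeric(0)
  for (g in blob_sizes) {
    if (L < g) next
    dmax <- patterning_delta(segA, segB, g)
    if (dmax <= 0) next
    vals <- c(vals, patterning_delta(isA, isB, g) / dmax)
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Wootton-Federhen sequence complexity
#'
#' Entropy (K2) form by default: `-sum_a (n_a/L) log20(n_a/L)`, bounded in
#' `[0, 1]`. The multinomial (K1) form,
#' `(1/L) log20( L! / prod_a n_a! )`, is available via `form = "k1"`.
#'
#' @param seq ungapped amino-acid string.
#' @param form `"k2"` (entropy, default) or `"k1"` (multinomial).
#' @return complexity in `[0, 1]`.
#' @export
wf_complexity <- function(seq, form = c("k2", "k1")) {
  validate_seq(seq)
  wf_core(aa_counts(aa_chars(seq)), match.arg(form))
}

wf_core <- function(n, form = "k2") {
  L <- sum(n)
  if (form == "k2") {
    p <- n[n > 0] / L
    -sum(p * log(p, base = 20))
  } else {
    (lgamma(L + 1) - sum(lgamma(n + 1))) / (L * log(20))
  }
}

hh_net_charge <- function(counts, pH, pka) {
  pos <- c(1, unname(counts[c("K", "R", "H")]))
  ppos <- unname(pka[c("Nterm", "K", "R", "H")])
  neg <- c(1, unname(counts[c("D", "E", "C", "Y")]))
  pneg <- unname(pka[c("Cterm", "D", "E", "C", "Y")])
  sum(pos / (1 + 10^(pH - ppos))) - sum(neg / (1 + 10^(pneg - pH)))
}

#' Isoelectric point by Henderson-Hasselbalch bisection
#'
#' Finds the pH at which the net charge (free termini plus D, E, C, Y, H, K,
#' R side chains under the given pKa table) crosses zero, by bisection to
#' `|charge| < 1e-4`.
#'
#' @param seq ungapped amino-acid string.
#' @param pka named pKa vector (defaults to the EMBOSS set, which lacks an
#'   H pKa entry in some tables; here H = 6.5).
#' @return pI in (0, 14).
#' @export
isoelectric_point <- function(seq, pka = EMBOSS_PKA) {
  validate_seq(seq)
  pi_core(aa_counts(aa_chars(seq)), pka)
}

pi_core <- function(counts, pka = EMBOSS_PKA) {
  if (!"H" %in% names(pka)) pka <- c(pka, H = 6.5)
  pos <- c(1, unname(counts[c("K", "R", "H")]))
  ppos <- unname(pka[c("Nterm", "K", "R", "H")])
  neg <- c(1, unname(counts[c("D", "E", "C", "Y")]))
  pneg <- unname(pka[c("Cterm", "D", "E", "C", "Y")])
  lo <- 0; hi <- 14
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    q <- sum(pos / (1 + 10^(mid - ppos))) - sum(neg / (1 + 10^(pneg - mid)))
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Density of motif matches
#'
#' Matches of a residue-class regular expression, counted at every anchor
#' (start) position so overlapping matches each count; optionally excluding
#' matches whose anchor is conservation-masked (a masked anchor means the
#' motif is conserved, and "non-conserved motif density" excludes it).
#'
#' @param seq ungapped amino-acid string.
#' @param pattern regular expression, e.g. `"[ST]P"` for a proline-directed
#'   phosphosite.
#' @param mask optional logical vector (length of `seq`); `TRUE` = masked.
#' @return matches per residue, in `[0, 1]`.
#' @export
motif_density <- function(seq, pattern, mask = NULL) {
  validate_seq(seq)
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  anchors <- as.integer(m)
  anchors <- anchors[anchors > 0L]
  if (!is.null(mask) && length(anchors) > 0L)
    anchors <- anchors[!mask[anchors]]
  length(anchors) / nchar(seq)
}

#' Density of residues in homopolymer (or class) repeat runs
#'
#' @param seq ungapped amino-acid string.
#' @param residue single residue, or a character vector treated as a residue
#'   class (e.g. `c("D","E")` for acidic tracts).
#' @param min_run minimum run length counted as a repeat (default 4).
#' @return fraction of residues lying inside qualifying runs.
#' @export
repeat_density <- function(seq, residue, min_run = 4L) {
  validate_seq(seq)
  ch <- aa_chars(seq)
  r <- rle(ch %in% residue)
  sum(r$lengths[r$values & r$lengths >= min_run]) / length(ch)
}

#' Mean hydropathy under a named scale
#'
#' @param seq ungapped amino-acid string.
#' @param scale `"kd"` (Kyte-Doolittle) or a named numeric vector over the
#'   20 residues.
#' @return mean per-residue scale value.
#' @export
hydrophobicity <- function(seq, scale = "kd") {
  validate_seq(seq)
  tab <- if (is.character(scale) && identical(scale, "kd")) KD_SCALE else scale
  mean(tab[aa_chars(seq)])
}

feature_def <- function(name, family, type, ...) {
  list(name = name, family = family, type = type, params = list(...))
}

#' The default molecular feature catalog (82 features)
#'
#' The catalog covers the feature families repeatedly implicated in IDR
#' function: the 20 amino-acid fractions; residue-group fractions; length;
#' net charge with and without phosphorylation; charge patterning (kappa,
#' omega, SCD, charge asymmetry); Wootton-Federhen complexity;
#' isoelectric point; hydropathy; phosphosite-consensus and other motif
#' densities; and homopolymer repeat densities. Exactly 82 features, giving
#' 164-dimensional evolutionary signatures (mean-Z + log-variance-Z).
#' The catalog is plain data and fully user-replaceable: any list of
#' definitions with the same fields works everywhere a catalog is accepted
#' (see [read_catalog_config()]).
#'
#' @return a `feature_catalog` (list of feature definitions).
#' @export
default_catalog <- function() {
  if (!is.null(.catalog_cache$default)) return(.catalog_cache$default)
  defs <- list()
  add <- function(d) defs[[length(defs) + 1L]] <<- d
  for (a in AA20)
    add(feature_def(paste0("frac_", a), "composition", "aa_fraction",
                    residues = a))
  add(feature_def("length", "length", "length"))
  add(feature_def("net_charge", "charge", "net_charge"))
  add(feature_def("net_charge_phospho", "charge", "net_charge_phospho",
                  pattern = "[ST]P", phospho_charge = -2))
  add(feature_def("frac_charged", "composition", "aa_fraction",
                  residues = CHARGED))
  add(feature_def("frac_positive", "composition", "aa_fraction",
                  residues = POSITIVE))
  add(feature_def("frac_negative", "composition", "aa_fraction",
                  residues = NEGATIVE))
  add(feature_def("ncpr", "charge", "ncpr"))
  add(feature_def("charge_asymmetry", "charge", "charge_asymmetry"))
  add(feature_def("kappa", "patterning", "patterning", split = "kappa",
                  blob_sizes = c(5L, 6L)))
  add(feature_def("kappa_b5", "patterning", "patterning", split = "kappa",
                  blob_sizes = 5L))
  add(feature_def("kappa_b6", "patterning", "patterning", split = "kappa",
                  blob_sizes = 6L))
  add(feature_def("omega", "patterning", "patterning", split = "omega",
                  blob_sizes = c(5L, 6L)))
  add(feature_def("scd", "patterning", "scd"))
  add(feature_def("wf_complexity", "complexity", "complexity", form = "k2"))
  add(feature_def("wf_complexity_k1", "complexity", "complexity", form = "k1"))
  add(feature_def("isoelectric_point", "physicochemical", "pI"))
  add(feature_def("hydrophobicity_kd", "physicochemical", "hydrophobicity"))
  add(feature_def("omega_b5", "patterning", "patterning", split = "omega",
                  blob_sizes = 5L))
  add(feature_def("omega_b6", "patterning", "patterning", split = "omega",
                  blob_sizes = 6L))
  groups <- list(
    frac_hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"),
    frac_aromatic = c("F", "W", "Y"),
    frac_aliphatic = c("I", "L", "V"),
    frac_polar = c("N", "Q", "S", "T"),
    frac_tiny = c("A", "G", "S"),
    frac_gly_pro = c("G", "P"),
    frac_amide = c("N", "Q"),
    frac_hydroxyl = c("S", "T"),
    frac_disorder_promoting = c("A", "E", "G", "K", "P", "Q", "R", "S"),
    frac_order_promoting = c("C", "F", "I", "L", "N", "V", "W", "Y"),
    frac_QN = c("Q", "N"),
    frac_RG = c("R", "G"),
    frac_EK = c("E", "K"),
    frac_GS = c("G", "S"),
    frac_PEST = c("P", "E", "S", "T"),
    frac_basic_aromatic = c("K", "R", "F", "W", "Y"))
  for (g in names(groups))
    add(feature_def(g, "composition", "aa_fraction", residues = groups[[g]]))
  motifs <- c(motif_pdir = "[ST]P", motif_cdk = "[ST]P.[KR]",
              motif_ckii = "[ST]..[DE]", motif_ck1 = "S..[ST]",
              motif_pxxp = "P..P", motif_dibasic = "[KR][KR]",
              motif_diacidic = "[DE][DE]", motif_fg = "FG")
  for (m in names(motifs))
    add(feature_def(m, "motif", "motif", pattern = motifs[[m]]))
  reps <- list(rep_Q = "Q", rep_K = "K", rep_N = "N",
               rep_acidic = NEGATIVE, rep_basic = POSITIVE)
  for (r in names(reps))
    add(feature_def(r, "repeat", "repeat", residues = reps[[r]],
                    min_run = 4L))
  add(feature_def("longest_run", "repeat", "run_stat", kind = "longest"))
  add(feature_def("mean_run_length", "repeat", "run_stat", kind = "mean"))
  add(feature_def("longest_charged_run", "repeat", "run_stat",
                  kind = "longest_class", residues = CHARGED))
  add(feature_def("longest_uncharged_run", "repeat", "run_stat",
                  kind = "longest_not_class", residues = CHARGED))
  add(feature_def("hydrophobicity_kd_max5", "physicochemical", "hydro_win",
                  window = 5L, stat = "max"))
  add(feature_def("hydrophobicity_kd_min5", "physicochemical", "hydro_win",
                  window = 5L, stat = "min"))
  add(feature_def("hydrophobicity_kd_max9", "physicochemical", "hydro_win",
                  window = 9L, stat = "max"))
  add(feature_def("hydrophobicity_kd_min9", "physicochemical", "hydro_win",
                  window = 9L, stat = "min"))
  add(feature_def("hydrophobicity_kd_sd", "physicochemical", "hydro_sd"))
  add(feature_def("kd_autocorr1", "patterning", "kd_autocorr"))
  add(feature_def("ncpr_max5", "charge", "ncpr_win", window = 5L,
                  stat = "max"))
  add(feature_def("ncpr_min5", "charge", "ncpr_win", window = 5L,
                  stat = "min"))
  add(feature_def("ncpr_sd5", "charge", "ncpr_win", window = 5L,
                  stat = "sd"))
  add(feature_def("wf_complexity_min12", "complexity", "complexity_min",
                  window = 12L))
  .catalog_cache$default <- structure(defs, class = "feature_catalog")
  .catalog_cache$default
}

.catalog_cache <- new.env(parent = emptyenv())

#' @rdname default_catalog
#' @param catalog a `feature_catalog`.
#' @export
catalog_names <- function(catalog)
  vapply(catalog, `[[`, character(1L), "name")

#' @export
print.feature_catalog <- function(x, ...) {
  fam <- table(vapply(x, `[[`, character(1L), "family"))
  cat(sprintf("<feature_catalog> %d features: %s\n", length(x),
              paste(names(fam), fam, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read / write a feature catalog from a structured config file
#'
#' Catalogs are plain data (name, family, type, params per feature), stored
#' as JSON so the full feature set is user-replaceable without touching code.
#'
#' @param path JSON file.
#' @return a `feature_catalog`.
#' @export
read_catalog_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  defs <- lapply(raw, function(d) {
    d$params <- lapply(d$params, function(p) unlist(p, use.names = FALSE))
    d
  })
  nm <- vapply(defs, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("duplicate feature names in catalog config")
  structure(defs, class = "feature_catalog")
}

#' @rdname read_catalog_config
#' @param catalog a `feature_catalog`.
#' @export
write_catalog_config <- function(catalog, path) {
  jsonlite::write_json(unclass(catalog), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

eval_feature <- function(def, ctx) {
  p <- def$params
  switch(def$type,
    aa_fraction = sum(ctx$counts[p$residues]) / ctx$L,
    length = ctx$L,
    net_charge = ctx$nplus - ctx$nminus,
    net_charge_phospho = {
      m <- gregexpr(paste0("(?=", p$pattern, ")"), ctx$seq, perl = TRUE)[[1L]]
      nsite <- sum(as.integer(m) > 0L)
      ctx$nplus - ctx$nminus + p$phospho_charge * nsite
    },
    ncpr = (ctx$nplus - ctx$nminus) / ctx$L,
    charge_asymmetry = {
      fp <- ctx$nplus / ctx$L; fm <- ctx$nminus / ctx$L
      if (fp + fm == 0) NA_real_ else (fp - fm)^2 / (fp + fm)
    },
    patterning = patterning_core(ctx$ch, p$split, p$blob_sizes),
    scd = scd_core(ctx$ch),
    complexity = wf_core(ctx$counts, p$form),
    pI = pi_core(ctx$counts),
    hydrophobicity = mean(KD_SCALE[ctx$ch]),
    motif = {
      m <- gregexpr(paste0("(?=", p$pattern, ")"), ctx$seq, perl = TRUE)[[1L]]
      anchors <- as.integer(m)
      anchors <- anchors[anchors > 0L]
      if (!is.null(ctx$mask) && length(anchors) > 0L)
        anchors <- anchors[!ctx$mask[anchors]]
      length(anchors) / ctx$L
    },
    `repeat` = {
      r <- ctx$runs
      hit <- r$lengths >= p$min_run
      if (length(p$residues) == 1L) {
        sum(r$lengths[hit & r$values == p$residues]) / ctx$L
      } else {
        rc <- rle(ctx$ch %in% p$residues)
        sum(rc$lengths[rc$values & rc$lengths >= p$min_run]) / ctx$L
      }
    },
    run_stat = {
      r <- ctx$runs
      switch(p$kind,
        longest = max(r$lengths) / ctx$L,
        mean = mean(r$lengths),
        longest_class = {
          rc <- rle(ctx$ch %in% p$residues)
          hits <- rc$lengths[rc$values]
          if (length(hits)) max(hits) / ctx$L else 0
        },
        longest_not_class = {
          rc <- rle(ctx$ch %in% p$residues)
          hits <- rc$lengths[!rc$values]
          if (length(hits)) max(hits) / ctx$L else 0
        })
    },
    hydro_win = {
      if (ctx$L < p$window) NA_real_ else {
        cs <- c(0, cumsum(KD_SCALE[ctx$ch]))
        i <- seq_len(ctx$L - p$window + 1L)
        v <- (cs[i + p$window] - cs[i]) / p$window
        if (p$stat == "max") max(v) else min(v)
      }
    },
    hydro_sd = if (ctx$L < 2L) NA_real_ else stats::sd(KD_SCALE[ctx$ch]),
    kd_autocorr = {
      v <- KD_SCALE[ctx$ch]
      a <- v[-ctx$L]; b <- v[-1L]
      if (ctx$L < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
      else stats::cor(a, b)
    },
    ncpr_win = {
      if (ctx$L < p$window) NA_real_ else {
        q <- ifelse(ctx$ch %in% POSITIVE, 1,
                    ifelse(ctx$ch %in% NEGATIVE, -1, 0))
        cs <- c(0, cumsum(q))
        i <- seq_len(ctx$L - p$window + 1L)
        v <- (cs[i + p$window] - cs[i]) / p$window
        switch(p$stat, max = max(v), min = min(v),
               sd = if (length(v) < 2L) NA_real_ else stats::sd(v))
      }
    },
    complexity_min = {
      if (ctx$L < p$window) NA_real_ else {
        # incremental sliding-window entropy: only two counts change per step
        w <- p$window
        idx <- ctx$idx
        term <- numeric(w + 1L)                 # -(n/w) log20(n/w), n = 0..w
        nn <- seq_len(w)
        term[nn + 1L] <- -(nn / w) * log(nn / w, base = 20)
        n <- tabulate(idx[seq_len(w)], 20L)
        h <- sum(term[n + 1L])
        hmin <- h
        for (i in seq_len(ctx$L - w)) {
          out <- idx[i]; inn <- idx[i + w]
          if (out != inn) {
            h <- h - term[n[out] + 1L] - term[n[inn] + 1L]
            n[out] <- n[out] - 1L; n[inn] <- n[inn] + 1L
            h <- h + term[n[out] + 1L] + term[n[inn] + 1L]
            if (h < hmin) hmin <- h
          }
        }
        hmin
      }
    },
    stop("unknown feature type: ", def$type))
}

#' Compute all catalog features for one sequence
#'
#' @param seq ungapped amino-acid string.
#' @param catalog a `feature_catalog` (default: [default_catalog()]).
#' @param mask optional per-residue logical conservation mask, used by motif
#'   features to exclude conserved (masked) anchors.
#' @return named numeric vector, one value per catalog feature; `NA` where a
#'   feature's definedness predicate fails.
#' @export
compute_features <- function(seq, catalog = default_catalog(), mask = NULL) {
  validate_seq(seq)
  ch <- aa_chars(seq)
  idx <- match(ch, AA20)
  counts <- tabulate(idx, 20L); names(counts) <- AA20
  ctx <- list(seq = seq, ch = ch, idx = idx, L = length(ch), counts = counts,
              nplus = sum(ch %in% POSITIVE), nminus = sum(ch %in% NEGATIVE),
              runs = rle(ch), mask = mask)
  vals <- vapply(catalog, eval_feature, numeric(1L), ctx = ctx)
  names(vals) <- catalog_names(catalog)
  vals
}

# shared per-sequence patterning bundle: kappa/omega ratios at blobs 5 and 6
patterning_bundle <- function(ch) {
  out <- c(k5 = NA_real_, k6 = NA_real_, o5 = NA_real_, o6 = NA_real_)
  L <- length(ch)
  kA <- as.numeric(ch %in% POSITIVE); kB <- as.numeric(ch %in% NEGATIVE)
  oA <- as.numeric(ch %in% c("P", CHARGED)); oB <- 1 - oA
  one <- function(isA, isB, g) {
    nA <- sum(isA); nB <- sum(isB)
    segA <- c(rep(1, nA), rep(0, L - nA))
    segB <- c(rep(0, L - nB), rep(1, nB))
    dmax <- patterning_delta(segA, segB, g)
    if (dmax <= 0) return(NA_real_)
    patterning_delta(isA, isB, g) / dmax
  }
  if (sum(kA) + sum(kB) > 0) {
    if (L >= 5L) out["k5"] <- one(kA, kB, 5L)
    if (L >= 6L) out["k6"] <- one(kA, kB, 6L)
  }
  if (sum(oA) > 0) {
    if (L >= 5L) out["o5"] <- one(oA, oB, 5L)
    if (L >= 6L) out["o6"] <- one(oA, oB, 6L)
  }
  out
}

mean_defined <- function(x) if (all(is.na(x))) NA_real_ else mean(x,
                                                                  na.rm = TRUE)

# parse a residue-class regular expression ("[ST]P.[KR]") into per-position
# 20-residue flag vectors; NULL when the pattern uses other regex syntax
# (then the gregexpr path is used instead)
parse_class_pattern <- function(pattern) {
  if (grepl("[^A-Z.\\[\\]]", pattern)) return(NULL)
  flags <- list()
  i <- 1L
  ch <- strsplit(pattern, "")[[1L]]
  while (i <= length(ch)) {
    if (ch[i] == ".") {
      flags[[length(flags) + 1L]] <- rep(TRUE, 20L)
      i <- i + 1L
    } else if (ch[i] == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(ch) && ch[j] != "]") { set <- c(set, ch[j]); j <- j + 1L }
      if (j > length(ch)) return(NULL)
      flags[[length(flags) + 1L]] <- AA20 %in% set
      i <- j + 1L
    } else {
      flags[[length(flags) + 1L]] <- AA20 == ch[i]
      i <- i + 1L
    }
  }
  if (length(flags) == 0L) NULL else flags
}

motif_counts_batch <- function(seqs, idxs, pattern) {
  flags <- parse_class_pattern(pattern)
  if (!is.null(flags))
    return(vapply(idxs, cpp_motif_count, numeric(1L), flags = flags))
  vapply(seqs, function(s)
    sum(as.integer(gregexpr(paste0("(?=", pattern, ")"), s,
                            perl = TRUE)[[1L]]) > 0L), numeric(1L))
}

#' Feature matrix for a collection of sequences
#'
#' Batched implementation sharing per-sequence intermediates (residue
#' counts, runs, window cumulative sums, patterning deltas) across the
#' catalog; agrees with [compute_features()] cell for cell.
#'
#' @param seqs character vector of ungapped sequences (named).
#' @param catalog a `feature_catalog`.
#' @return matrix (sequences x features).
#' @export
feature_matrix <- function(seqs, catalog = default_catalog()) {
  n <- length(seqs)
  Fn <- length(catalog)
  nm <- catalog_names(catalog)
  if (n == 0L)
    return(matrix(numeric(0), 0L, Fn, dimnames = list(NULL, nm)))
  for (s in seqs) validate_seq(s)
  chs <- strsplit(seqs, "")
  idxs <- lapply(chs, match, AA20)
  Ls <- lengths(chs)
  C <- t(vapply(idxs, tabulate, numeric(20L), nbins = 20L))
  colnames(C) <- AA20
  nplus <- C[, "K"] + C[, "R"]; nminus <- C[, "D"] + C[, "E"]
  kdvec <- lapply(chs, function(ch) unname(KD_SCALE[ch]))
  member_flags <- function(residues) AA20 %in% residues
  needs_pat <- any(vapply(catalog, function(d) d$type == "patterning",
                          logical(1L)))
  pat <- if (needs_pat) {
    m <- t(vapply(idxs, cpp_pat_bundle, numeric(4L)))
    colnames(m) <- c("k5", "k6", "o5", "o6")
    m
  }
  needs_runstat <- any(vapply(catalog, function(d) d$type == "run_stat",
                              logical(1L)))
  rstats <- if (needs_runstat)
    t(vapply(idxs, cpp_runstats, numeric(4L),
             member = member_flags(CHARGED)))
  qvec <- lapply(chs, function(ch)
    ifelse(ch %in% POSITIVE, 1, ifelse(ch %in% NEGATIVE, -1, 0)))
  win_stat <- function(v, w, stat) {
    L <- length(v)
    if (L < w) return(NA_real_)
    cs <- c(0, cumsum(v))
    i <- seq_len(L - w + 1L)
    x <- (cs[i + w] - cs[i]) / w
    switch(stat, max = max(x), min = min(x),
           sd = if (length(x) < 2L) NA_real_ else stats::sd(x))
  }
  out <- matrix(NA_real_, n, Fn, dimnames = list(names(seqs), nm))
  for (j in seq_len(Fn)) {
    def <- catalog[[j]]; p <- def$params
    out[, j] <- switch(def$type,
      aa_fraction = rowSums(C[, p$residues, drop = FALSE]) / Ls,
      length = Ls,
      net_charge = nplus - nminus,
      net_charge_phospho = nplus - nminus + p$phospho_charge *
        motif_counts_batch(seqs, idxs, p$pattern),
      ncpr = (nplus - nminus) / Ls,
      charge_asymmetry = {
        fp <- nplus / Ls; fm <- nminus / Ls
        ifelse(fp + fm == 0, NA_real_, (fp - fm)^2 / (fp + fm))
      },
      patterning = {
        cols <- paste0(if (p$split == "kappa") "k" else "o",
                       p$blob_sizes)
        apply(pat[, cols, drop = FALSE], 1L, mean_defined)
      },
      scd = vapply(idxs, cpp_scd, numeric(1L)),
      complexity = {
        if (p$form == "k2") {
          P <- C / Ls
          -rowSums(ifelse(P > 0, P * log(P, base = 20), 0))
        } else {
          (lgamma(Ls + 1) - rowSums(lgamma(C + 1))) / (Ls * log(20))
        }
      },
      pI = apply(C, 1L, pi_core),
      hydrophobicity = as.numeric(C %*% KD_SCALE[AA20]) / Ls,
      motif = motif_counts_batch(seqs, idxs, p$pattern) / Ls,
      `repeat` = {
        flags <- member_flags(p$residues)
        vapply(idxs, cpp_run_frac, numeric(1L), member = flags,
               min_run = p$min_run)
      },
      run_stat = {
        same_member <- is.null(p$residues) || setequal(p$residues, CHARGED)
        rs <- if (same_member && !is.null(rstats)) rstats else
          t(vapply(idxs, cpp_runstats, numeric(4L),
                   member = member_flags(p$residues)))
        switch(p$kind, longest = rs[, 3L], mean = rs[, 4L],
               longest_class = rs[, 1L], longest_not_class = rs[, 2L])
      },
      hydro_win = vapply(kdvec, win_stat, numeric(1L), w = p$window,
                         stat = p$stat),
      hydro_sd = vapply(kdvec, function(v)
        if (length(v) < 2L) NA_real_ else stats::sd(v), numeric(1L)),
      kd_autocorr = vapply(kdvec, function(v) {
        L <- length(v)
        if (L < 3L) return(NA_real_)
        a <- v[-L]; b <- v[-1L]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
        else stats::cor(a, b)
      }, numeric(1L)),
      ncpr_win = vapply(qvec, win_stat, numeric(1L), w = p$window,
                        stat = p$stat),
      complexity_min = vapply(idxs, cpp_cmin, numeric(1L), w = p$window),
      stop("unknown feature type: ", def$type))
  }
  out
}
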