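# Per-column and local evolutionary rates on an IDR alignment, and a
# two-state rate-contrast HMM that masks preferentially conserved segments
# (SLiM-like elements). This is a declared simplification of full
# phylo-HMMs: gaps are treated as missing data and no indel or motif
# emission model is used; externally computed masks can be supplied directly
# to the simulator instead.

RATE_BOUNDS <- c(1e-4, 100)

# integer-encode alignment columns; NA = gap (missing data)
alignment_states <- function(set) {
  mat <- do.call(rbind, strsplit(unname(set$rows), ""))
  states <- matrix(match(mat, AA20), nrow = nrow(mat))
  rownames(states) <- names(set$rows)
  states
}

# log-likelihood of each column under branch lengths scaled by r
# (Felsenstein pruning, vectorized over columns, per-node rescaling)
pruning_loglik <- function(states, tree, model, r) {
  ntip <- length(tree$tip.label)
  nc <- ncol(states)
  states <- states[tree$tip.label, , drop = FALSE]
  tree <- stats::reorder(tree, "postorder")
  msg <- vector("list", max(tree$edge))
  logscale <- matrix(0, max(tree$edge), nc)
  tipmsg <- function(i) {
    m <- matrix(1, 20L, nc)
    obs <- !is.na(states[i, ])
    if (any(obs)) {
      m[, obs] <- 0
      m[cbind(states[i, obs], which(obs))] <- 1
    }
    m
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    cm <- if (child <= ntip) tipmsg(child) else msg[[child]]
    P <- model_P(model, r * tree$edge.length[e])
    up <- P %*% cm
    if (is.null(msg[[parent]])) {
      msg[[parent]] <- up
      logscale[parent, ] <- logscale[child, ]
    } else {
      msg[[parent]] <- msg[[parent]] * up
      logscale[parent, ] <- logscale[parent, ] + logscale[child, ]
      mx <- apply(msg[[parent]], 2L, max)
      mx[mx <= 0] <- 1
      msg[[parent]] <- sweep(msg[[parent]], 2L, mx, "/")
      logscale[parent, ] <- logscale[parent, ] + log(mx)
    }
  }
  rootnode <- ntip + 1L
  log(colSums(model$pi * msg[[rootnode]])) + logscale[rootnode, ]
}

#' Maximum-likelihood per-column evolutionary rates
#'
#' For each alignment column, finds the scalar rate multiplier `r` in
#' `[1e-4, 100]` maximizing the pruning-algorithm likelihood of the column
#' under branch lengths scaled by `r`. Gap cells are missing data; columns
#' with fewer than 2 residues get `NA`.
#'
#' @param set an `ortholog_set` (gapped alignment).
#' @param tree `ape::phylo` covering the set's species (extra tips pruned).
#' @param model a `subst_model`.
#' @param grid_size number of log-spaced grid points scanned before local
#'   refinement.
#' @return numeric vector of per-column rates (`NA` where undefined).
#' @export
column_rates <- function(set, tree, model = default_subst_model(),
                         grid_size = 25L) {
  sp <- names(set$rows)
  if (!all(sp %in% tree$tip.label))
    stop("tree lacks species: ",
         paste(setdiff(sp, tree$tip.label), collapse = ", "))
  if (length(setdiff(tree$tip.label, sp)) > 0L)
    tree <- ape::keep.tip(tree, sp)
  states <- alignment_states(set)
  nc <- ncol(states)
  nobs <- colSums(!is.na(states))
  est <- rep(NA_real_, nc)
  usable <- which(nobs >= 2L)
  if (length(usable) == 0L) return(est)
  grid <- exp(seq(log(RATE_BOUNDS[1L]), log(RATE_BOUNDS[2L]),
                  length.out = grid_size))
  ll <- vapply(grid, function(r)
    pruning_loglik(states[, usable, drop = FALSE], tree, model, r),
    numeric(length(usable)))
  ll <- matrix(ll, nrow = length(usable))
  best <- apply(ll, 1L, which.max)
  for (k in seq_along(usable)) {
    j <- usable[k]
    lo <- grid[max(1L, best[k] - 1L)]
    hi <- grid[min(grid_size, best[k] + 1L)]
    if (lo == hi) { est[j] <- lo; next }
    col <- states[, j, drop = FALSE]
    opt <- stats::optimize(function(logr)
      pruning_loglik(col, tree, model, exp(logr)),
      interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-3)
    est[j] <- exp(opt$maximum)
  }
  est
}

#' Local (windowed) evolutionary rates
#'
#' Centered moving average of the column rates over a window (default 31
#' columns), ignoring missing columns; edge windows are truncated.
#'
#' @param column_rates vector from [column_rates()].
#' @param window odd window size in alignment columns.
#' @return vector of local rates, same length.
#' @export
local_rates <- function(column_rates, window = 31L) {
  n <- length(column_rates)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    w <- column_rates[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1L))
}

# log-space forward-backward for the 2-state chain
forward_backward <- function(logem, log_trans, log_init) {
  n <- nrow(logem)
  la <- matrix(-Inf, n, 2L); lb <- matrix(0, n, 2L)
  la[1L, ] <- log_init + logem[1L, ]
  for (i in 2:n)
    for (s in 1:2)
      la[i, s] <- logem[i, s] +
        max(la[i - 1L, ] + log_trans[, s]) +
        log(sum(exp(la[i - 1L, ] + log_trans[, s] -
                    max(la[i - 1L, ] + log_trans[, s]))))
  for (i in (n - 1L):1L)
    for (s in 1:2) {
      v <- log_trans[s, ] + logem[i + 1L, ] + lb[i + 1L, ]
      lb[i, s] <- max(v) + log(sum(exp(v - max(v))))
    }
  ll <- max(la[n, ]) + log(sum(exp(la[n, ] - max(la[n, ]))))
  lg <- la + lb - ll
  list(gamma = exp(lg), loglik = ll, la = la, lb = lb)
}

#' Conserved-segment mask via a two-state rate-contrast HMM
#'
#' Columns are emitted either from a background state evolving at the local
#' rate or from a conserved state at `rho * local` (`rho < 1`). Emission
#' probabilities are the column pruning likelihoods under each state's rate;
#' `rho` and the transition probabilities are fitted by EM with random
#' restarts; the mask is the thresholded posterior (`> 0.5`) of the
#' conserved state. With fewer columns than the window, or with no rate
#' contrast (e.g. an all-invariant alignment, where the two states collapse
#' and posteriors sit at 0.5), the mask is all-false.
#'
#' @inheritParams column_rates
#' @param col_rates,loc_rates precomputed rate vectors (computed if NULL).
#' @param window local-rate window (default 31).
#' @param rho_init initial conserved-state rate fraction (default 0.3).
#' @param self_prob initial transition self-probability (default 0.95).
#' @param n_restarts EM restarts with jittered initial rho (default 3).
#' @param max_iter EM iterations per restart.
#' @param seed seed for the restarts (logged in the result).
#' @return list: `mask` (logical per column), `posterior`, `rho`,
#'   `column_rates`, `local_rates`, `loglik`, `seed`.
#' @export
constraint_mask <- function(set, tree, model = default_subst_model(),
                            col_rates = NULL, loc_rates = NULL,
                            window = 31L, rho_init = 0.3, self_prob = 0.95,
                            n_restarts = 3L, max_iter = 30L, seed = 1L) {
  sp <- names(set$rows)
  if (length(setdiff(tree$tip.label, sp)) > 0L) tree <- ape::keep.tip(tree, sp)
  if (is.null(col_rates)) col_rates <- column_rates(set, tree, model)
  if (is.null(loc_rates)) loc_rates <- local_rates(col_rates, window)
  nc <- length(col_rates)
  empty <- list(mask = rep(FALSE, nc), posterior = rep(0, nc),
                rho = NA_real_, column_rates = col_rates,
                local_rates = loc_rates, loglik = NA_real_, seed = seed)
  if (nc < window) {
    warning("fewer columns (", nc, ") than window (", window,
            "); mask all-false")
    return(empty)
  }
  states <- alignment_states(set)
  ok <- which(!is.na(col_rates) & !is.na(loc_rates) & loc_rates > 0)
  if (length(ok) < 2L) return(empty)
  # quantized per-column rates so emission vectors batch into few pruning
  # calls; cached per rho grid point across EM iterations and restarts
  loc_q <- signif(pmin(pmax(loc_rates[ok], RATE_BOUNDS[1L]),
                       RATE_BOUNDS[2L]), 2)
  ll_at_rates <- function(r_vec) {
    out <- numeric(length(ok))
    for (u in unique(r_vec)) {
      sel <- which(r_vec == u)
      out[sel] <- pruning_loglik(states[, ok[sel], drop = FALSE], tree,
                                 model, u)
    }
    out
  }
  ll_bg <- ll_at_rates(loc_q)
  rho_grid <- seq(0.05, 0.9, by = 0.05)
  llcache <- new.env(parent = emptyenv())
  ll_cons_at <- function(rho) {
    key <- format(rho)
    if (is.null(llcache[[key]]))
      llcache[[key]] <- ll_at_rates(signif(pmin(pmax(
        rho * loc_q, RATE_BOUNDS[1L]), RATE_BOUNDS[2L]), 2))
    llcache[[key]]
  }
  set.seed(seed)
  rho_starts <- c(rho_init,
                  sample(rho_grid, max(0L, n_restarts - 1L)))
  best <- NULL
  for (rho0 in rho_starts) {
    rho <- rho_grid[which.min(abs(rho_grid - rho0))]
    p_self <- c(self_prob, self_prob)
    init <- c(0.9, 0.1)
    prev_ll <- -Inf
    fb <- NULL
    for (it in seq_len(max_iter)) {
      logem <- cbind(ll_bg, ll_cons_at(rho))
      log_trans <- log(matrix(c(p_self[1L], 1 - p_self[1L],
                                1 - p_self[2L], p_self[2L]),
                              2L, 2L, byrow = TRUE))
      fb <- forward_backward(logem, log_trans, log(init))
      if (abs(fb$loglik - prev_ll) < 1e-6) break
      prev_ll <- fb$loglik
      g <- fb$gamma
      # expected transition counts (numerically adequate at these sizes)
      xi <- matrix(0, 2L, 2L)
      for (i in seq_len(nrow(logem) - 1L))
        for (s in 1:2) for (u in 1:2) {
          v <- fb$la[i, s] + log_trans[s, u] + logem[i + 1L, u] +
            fb$lb[i + 1L, u] - fb$loglik
          xi[s, u] <- xi[s, u] + exp(v)
        }
      rs <- rowSums(xi); rs[rs == 0] <- 1
      p_self <- pmin(pmax(diag(xi) / rs, 0.5), 0.999)
      init <- pmax(g[1L, ], 1e-3); init <- init / sum(init)
      if (sum(g[, 2L]) > 1e-6) {
        gain <- vapply(rho_grid, function(r)
          sum(g[, 2L] * ll_cons_at(r)), numeric(1L))
        rho <- rho_grid[which.max(gain)]
      }
    }
    if (is.null(best) || prev_ll > best$loglik)
      best <- list(loglik = prev_ll, gamma = fb$gamma, rho = rho)
  }
  posterior <- rep(0, nc)
  posterior[ok] <- best$gamma[, 2L]
  # guard against the conserved state soaking up estimation noise: the
  # two-state fit must beat one background state by a BIC-style margin
  # (3 extra parameters: rho + 2 transition probabilities)
  lrt_gain <- best$loglik - sum(ll_bg)
  if (best$rho > 0.9 || lrt_gain < 1.5 * log(length(ok)))
    posterior[] <- 0
  list(mask = posterior > 0.5, posterior = posterior, rho = best$rho,
       column_rates = col_rates, local_rates = loc_rates,
       loglik = best$loglik, lrt_gain = lrt_gain, seed = seed)
}

#' Total evolutionary divergence of a region
#'
#' @param tree `ape::phylo` fitted to the region.
#' @return sum of branch lengths.
#' @export
region_divergence <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

#' Write a rate profile as TSV
#'
#' @param profile list from [constraint_mask()].
#' @param path output path.
#' @export
write_rate_profile <- function(profile, path) {
  df <- data.frame(column = seq_along(profile$column_rates),
                   rate = profile$column_rates,
                   local_rate = profile$local_rates,
                   posterior = profile$posterior,
                   mask = profile$mask)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
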