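# Independent oracles used to validate the package's numerics. These are
# deliberately naive implementations (exhaustive enumeration, quadrature,
# full-matrix DP) kept separate from the code paths they check.

# Brute-force tree likelihood: enumerate all internal-node state assignments
# and sum pi(root) * prod(P) over them, averaging over gamma categories.
# Feasible for <= 4 leaves and a handful of sites.
brute_force_logL <- function(ntree, model, alignment) {
  td <- placeprof:::tree_data(ntree)
  states <- lapply(alignment[ntree$phylo$tip.label], placeprof:::encode_aa)
  nsite <- length(states[[1L]])
  internals <- setdiff(seq_len(td$nnode), seq_len(td$ntip))
  grid <- as.matrix(do.call(expand.grid, rep(list(1:20), length(internals))))
  colnames(grid) <- as.character(internals)
  k <- model$k
  total <- 0
  for (s in seq_len(nsite)) {
    site_lik_cats <- numeric(k)
    for (cat in seq_len(k)) {
      # joint likelihood of every internal-state assignment:
      # pi(root) * prod over edges of P[parent_state, child_state]
      lik <- model$freqs[grid[, as.character(td$root)]]
      for (nd in seq_len(td$nnode)) {
        if (nd == td$root) next
        P <- substitution_probability(model, td$len_of[nd], cat)
        par_state <- grid[, as.character(td$parent[nd])]
        child_state <- if (nd <= td$ntip) {
          st <- states[[ntree$phylo$tip.label[nd]]][s]
          if (is.na(st)) next   # missing data: sum_child P = 1
          rep(st, nrow(grid))
        } else grid[, as.character(nd)]
        lik <- lik * P[cbind(par_state, child_state)]
      }
      site_lik_cats[cat] <- sum(lik)
    }
    total <- total + log(mean(site_lik_cats))
  }
  total
}

# Exhaustive affine-gap Smith-Waterman (full three-matrix DP, score only).
# A gap of length L costs open + L * ext.
sw_oracle <- function(a, b, submat, open, ext) {
  av <- match(strsplit(a, "")[[1]], rownames(submat))
  bv <- match(strsplit(b, "")[[1]], rownames(submat))
  m <- length(av); n <- length(bv)
  NEG <- -1e30
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Quadrature oracle for discrete-gamma category rates: conditional mean of
# gamma(shape = a, rate = a) over each equal-probability quantile interval.
gamma_rates_oracle <- function(alpha, k) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  vapply(seq_len(k), function(i) {
    lo <- q[i]; hi <- q[i + 1]
    f <- function(x) x * stats::dgamma(x, shape = alpha, rate = alpha)
    upper <- if (is.finite(hi)) hi else stats::qgamma(1 - 1e-12, alpha, rate = alpha)
    stats::integrate(f, lo, upper, rel.tol = 1e-10)$value * k
  }, 0)
}

random_aa_string <- function(n) {
  paste(sample(placeprof:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
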