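# Independent brute-force implementations used as oracles. These are
# written as literally as possible (explicit loops, table()-based
# frequencies) and share no code with the package internals.

# Heterogeneity of a {0,1,NA} cells x sites matrix by exhaustive pair
# enumeration.
brute_force_heterogeneity <- function(states, min_shared_sites = 4) {
  n <- nrow(states)
  D <- c(); S <- c(); w <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- which(!is.na(states[i, ]) & !is.na(states[j, ]))
      k <- length(shared)
      if (k < min_shared_sites) next
      xi <- states[i, shared]; xj <- states[j, shared]
      D <- c(D, sum(xi != xj) / k)
      pattern <- paste(xi, xj)
      p <- as.numeric(table(pattern)) / k
      S <- c(S, -sum(p * log2(p)))
      w <- c(w, k)
    }
  }
  if (length(w) == 0) return(NA_real_)
  (sum(w * D) / sum(w)) * (sum(w * S) / sum(w))
}

# Rolling median with centred edge-truncated windows, written directly.
oracle_rolling_median <- function(x, window) {
  half <- floor(window / 2)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- max(1, i - half)
    hi <- min(length(x), i + half)
    out[i] <- stats::median(x[lo:hi])
  }
  out
}

# Sliding-window Z-scores, written directly.
oracle_sliding_z <- function(x, window) {
  half <- floor(window / 2)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    s <- stats::sd(w)
    out[i] <- if (is.na(s) || s == 0) 0 else (x[i] - mean(w)) / s
  }
  out
}

# Exact rank-sum p-value by exhaustive enumeration over all
# choose(n, n1) group assignments (feasible for small n).
oracle_ranksum_exact <- function(values, groups,
                                 alternative = "two.sided") {
  groups <- as.factor(groups)
  g1 <- levels(groups)[1]
  n <- length(values)
  n1 <- sum(groups == g1)
  ranks <- rank(values)
  w_obs <- sum(ranks[groups == g1])
  combos <- utils::combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  switch(alternative,
         greater = mean(w_all >= w_obs - 1e-9),
         less = mean(w_all <= w_obs + 1e-9),
         two.sided = {
           mu <- mean(w_all)
           mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
         })
}

# Area under the ROC curve for scores of positives vs negatives,
# via the rank-sum identity.
rank_auc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n_pos <- length(scores_pos)
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * length(scores_neg))
}
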