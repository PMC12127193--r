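# Independent brute-force oracles used to check the fast implementations.
# These deliberately share no code with the package internals.

# AUROC by exhaustive pair counting: wins + half-ties over all
# (responder, non-responder) pairs.
oracle_auroc_pairs <- function(levels, labels) {
  pos <- levels[as.logical(labels)]
  neg <- levels[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Best Youden J over a dense threshold grid (every observed value +/- eps
# and midpoints), both directions.
oracle_youden_scan <- function(levels, labels) {
  y <- as.logical(labels)
  eps <- 1e-9 * max(1, diff(range(levels)))
  cand <- sort(unique(c(levels - eps, levels, levels + eps)))
  best <- -Inf
  for (t in cand) {
    for (ge in c(TRUE, FALSE)) {
      pred <- if (ge) levels >= t else levels <= t
      J <- mean(pred[y]) + mean(!pred[!y]) - 1
      if (J > best) best <- J
    }
  }
  best
}

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# support of cell `a` with all margins fixed.
oracle_fisher_enum <- function(a, b, c, d) {
  m <- a + b          # favorable-stratum margin
  k <- a + c          # responder margin
  n_tot <- a + b + c + d
  support <- max(0, k - (n_tot - m)):min(m, k)
  probs <- vapply(support, function(x)
    exp(lchoose(m, x) + lchoose(n_tot - m, k - x) - lchoose(n_tot, k)),
    numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random marker/label instance with occasional ties; guarantees both classes.
random_instance <- function(n, seed, tie_prob = 0.5) {
  set.seed(seed)
  x <- if (runif(1) < tie_prob) round(runif(n, 0, 5), 1) else runif(n)
  repeat {
    y <- runif(n) < runif(1, 0.2, 0.8)
    if (any(y) && any(!y)) break
  }
  list(levels = x, labels = y)
}

# Complete-linkage merge heights by direct recomputation of pairwise-max
# distances over all cluster pairs (for tiny instances).
oracle_complete_linkage_heights <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(dmat[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# GSEA running-sum ES written out step by step (weight exponent 1).
oracle_gsea_es <- function(scores_desc, member_positions) {
  N <- length(scores_desc)
  nh <- length(member_positions)
  nr <- sum(abs(scores_desc[member_positions]))
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (i %in% member_positions) abs(scores_desc[i]) / nr
               else -1 / (N - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}
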