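# Independent brute-force references, deliberately naive O(N^2 m) double
# loops written against the definitions, not against the package internals.

# Cross entropy by explicit double loop over all (N - m)^2 template pairs.
oracle_cross_entropy <- function(u, v, m, r, fuzzy, n = 2) {
  N <- length(u)
  nt <- N - m
  phi <- function(w) {
    total <- 0
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        x <- u[i:(i + w - 1)]
        y <- v[j:(j + w - 1)]
        if (fuzzy) {
          x <- x - mean(x)
          y <- y - mean(y)
        }
        d <- max(abs(x - y))
        total <- total + if (fuzzy) exp(-d^n / r) else as.numeric(d < r)
      }
    }
    total / nt^2
  }
  a <- phi(m)
  b <- phi(m + 1)
  if (!fuzzy && b == 0) NA_real_ else -log(b / a)
}

# Two-sided Mann-Whitney p by full enumeration of label assignments.
oracle_mw_exact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  Us <- apply(combs, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs + 1e-8), mean(Us >= U_obs - 1e-8)))
}

# AUC by explicit concordant-pair counting.
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
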