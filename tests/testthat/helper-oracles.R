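# Independent oracles used to cross-check package computations.

# hypergeometric upper tail P(X >= k) by explicit combinatorial sum
hyper_upper_oracle <- function(n_u, n_a, n_b, k) {
  js <- seq(k, min(n_a, n_b))
  if (k > min(n_a, n_b)) return(0)
  sum(choose(n_a, js) * choose(n_u - n_a, n_b - js)) / choose(n_u, n_b)
}

# Benjamini-Hochberg step-up by direct definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# unit-cost edit distance by dynamic programming over symbol vectors
lev_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na
  d[1L, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (a[i] != b[j]))
    }
  }
  d[na + 1L, nb + 1L]
}

# AUC by exhaustive comparison of every (positive, negative) pair
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# two-sided Mann-Whitney p by full enumeration of group assignments
mw_exact_oracle <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(x), na)
  u_of <- function(sel) {
    aa <- x[sel]; bb <- x[-sel]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(idx, 2, u_of)
  mu <- na * (length(x) - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# perturbation factors by an independently coded dense construction:
# explicit loops over the edge list, then a QR solve
pf_oracle <- function(graph, delta_e) {
  m <- graph$members
  n <- length(m)
  de <- rep(0, n); names(de) <- m
  de[intersect(names(delta_e), m)] <-
    delta_e[intersect(names(delta_e), m)]
  B <- matrix(0, n, n, dimnames = list(m, m))
  e <- graph$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      nds <- sum(e$source == e$source[r])
      B[e$target[r], e$source[r]] <-
        B[e$target[r], e$source[r]] + e$beta[r] / nds
    }
  }
  qr.solve(diag(n) - B, de)
}

# residual of the fixed-point recurrence PF(i) = dE(i) + sum_j b PF(j)/Nds(j)
pf_residual <- function(graph, delta_e, pf) {
  m <- graph$members
  de <- rep(0, length(m)); names(de) <- m
  de[intersect(names(delta_e), m)] <-
    delta_e[intersect(names(delta_e), m)]
  res <- pf - de
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    nds <- sum(e$source == e$source[r])
    res[e$target[r]] <- res[e$target[r]] -
      e$beta[r] * pf[e$source[r]] / nds
  }
  max(abs(res))
}
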