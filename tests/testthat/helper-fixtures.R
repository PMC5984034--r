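# Shared fixtures and independent oracles.  Oracles deliberately use the
# plainest possible arithmetic (explicit loops, term-by-term sums) so they
# stay independent of the vectorized implementation paths they check.

# Term-by-term symmetric KL oracle (log base 2, 0*log0 = 0).
oracle_symmetric_kl <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  d <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) d <- d + p[k] * log2(p[k] / q[k])
    if (q[k] > 0) d <- d + q[k] * log2(q[k] / p[k])
  }
  d
}

# Naive triple-loop matrix product followed by row normalization.
oracle_blueprint_product <- function(vb, bt) {
  n <- nrow(vb); nl <- ncol(vb); K <- ncol(bt)
  out <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      s <- 0
      for (j in seq_len(nl)) s <- s + vb[i, j] * bt[j, k]
      out[i, k] <- s
    }
  }
  for (i in seq_len(n)) {
    rs <- sum(out[i, ])
    if (rs > 0) out[i, ] <- out[i, ] / rs
  }
  out
}

# One Dirichlet(alpha) draw.
rdirich <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# A random row-stochastic matrix with strictly positive entries.
random_stochastic <- function(n, K, alpha = 1) {
  t(replicate(n, rdirich(rep(alpha, K)) )) |>
    (\(m) (m + 1e-8) / (1 + K * 1e-8))()
}

# A small blueprint around random fingerprints.
random_blueprint <- function(n, K, species = "X", mask = NULL) {
  ts <- tract_set(sprintf("t%02d", seq_len(K)))
  connectivity_blueprint(random_stochastic(n, K), ts, vertex_mask = mask,
                         species = species, epsilon = 0)
}

# Manually assembled divergence matrix (all vertices unmasked).
manual_divergence <- function(values) {
  structure(list(values = values, row_mask = rep(TRUE, nrow(values)),
                 col_mask = rep(TRUE, ncol(values)), units = "bits"),
            class = "divergence_matrix")
}
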