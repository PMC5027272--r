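# Small reusable fixtures, built in code.

# A compact cohort model where the conditioning event (total term count)
# is common, so Monte-Carlo checks need few replicates.
small_query <- function(n = 0L, k = integer(), rho_free = TRUE) {
  mixture_query(N = 60, T_total = 16, q1 = 0.2, q2 = 0.5, k = k, n = n)
}

# Deterministic log2-scale matrix with named dimensions.
toy_matrix <- function(n_genes = 200, n_samples = 16, seed = 1, sd = 0.5) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 8, sd), n_genes, n_samples,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

halves_assignment <- function(x) {
  group_assignment(colnames(x)[seq_len(ncol(x) / 2)],
                   colnames(x)[-seq_len(ncol(x) / 2)])
}

# Textbook Benjamini-Hochberg step-up, written independently of bh_adjust:
# sort ascending, multiply by m/i, enforce monotonicity from the largest
# rank down, cap at 1, return in input order.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}
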