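# Independent brute-force oracles used to check the analytic tests, plus
# lazily-built shared fixtures. The oracles deliberately share no code with
# the package implementation.

# all permutations of 1..n, one per row (recursive construction)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# two-sided exact Spearman p-value by full enumeration over permutations
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    suppressWarnings(stats::cor(a, b, method = "pearson"))
  }
  obs <- rho_of(rx, ry)
  perms <- oracle_perms(n)
  vals <- apply(perms, 1, function(p) rho_of(rx, ry[p]))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# two-sided exact Mann-Whitney p-value by enumeration of group assignments
oracle_mw_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  u_of <- function(sel) sum(r[sel]) - n_a * (n_a + 1) / 2
  obs <- u_of(seq_len(n_a))
  mu <- n_a * n_b / 2
  sels <- utils::combn(n, n_a)
  vals <- apply(sels, 2, u_of)
  mean(abs(vals - mu) >= abs(obs - mu) - 1e-9)
}

# hand-written BH step-up: sort ascending, q_(i) = min_{j>=i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exact upper binomial tail from the definition
oracle_binom_tail <- function(k, n, p0 = 0.5) {
  sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
}

# shared fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# small dataset with moderate couplings, reused across test files
tiny_dataset <- function() {
  cached("tiny", simulate_dataset(synthetic_truth(
    seed = 42L, n_genes = 120L, beta_charged = 0.4, beta_disorder = 0.2,
    noise_sd = 0.5
  )))
}

# noise-free single-probe dataset for exact response recovery
noiseless_dataset <- function() {
  cached("noiseless", simulate_dataset(synthetic_truth(
    seed = 7L, n_genes = 60L, beta_charged = 0.5, beta_polar = 0,
    beta_hydrophobic = 0, beta_disorder = 0, gamma_gc = 0,
    noise_sd = 0, replicate_cv = 0, qc_sdlog2 = 0,
    probes_per_gene_range = c(1L, 1L),
    frac_multi_gene_probes = 0, frac_flag_fail = 0
  )))
}
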