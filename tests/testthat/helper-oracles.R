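# Independent oracles used across test files. These deliberately use
# different code paths (explicit factorial formulas, exhaustive
# enumeration, stats:: reference implementations) from the package.

# Two-sided exact p for an r x 2 table by brute-force enumeration of every
# margin-preserving table, probability from the factorial formula
# prod(R_i!) prod(C_j!) / (N! prod(cells!)).
oracle_fisher <- function(tab) {
  R <- rowSums(tab)
  C <- colSums(tab)
  N <- sum(tab)
  if (N == 0) return(1)
  logconst <- sum(lfactorial(R)) + sum(lfactorial(C)) - lfactorial(N)
  grid <- expand.grid(lapply(R, function(r) 0:r))
  grid <- grid[rowSums(grid) == C[1L], , drop = FALSE]
  logp <- apply(grid, 1L, function(x1) {
    logconst - sum(lfactorial(c(x1, R - x1)))
  })
  p <- exp(logp)
  p_obs <- exp(logconst - sum(lfactorial(tab)))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Exact conditional HWE p by enumerating every genotype triple (a, b, c)
# with a + b + c = n and matching minor-allele count, probability
# proportional to n! 2^b / (a! b! c!).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- 2 * n_aa + n_Aa
  probs <- numeric(0)
  obs_idx <- NA_integer_
  for (b in 0:n) for (cc in 0:(n - b)) {
    a <- n - b - cc
    if (2 * cc + b != n_minor) next
    probs <- c(probs, exp(lfactorial(n) + b * log(2) -
                            lfactorial(a) - lfactorial(b) - lfactorial(cc)))
    if (a == n_AA && b == n_Aa && cc == n_aa) obs_idx <- length(probs)
  }
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[obs_idx] * (1 + 1e-7)]))
}

# Best single breakpoint by exhaustive scan with stats::t.test (Welch).
oracle_best_breakpoint <- function(x, min_markers) {
  n <- length(x)
  s <- min_markers:(n - min_markers)
  p <- vapply(s, function(si) {
    stats::t.test(x[1:si], x[(si + 1):n])$p.value
  }, numeric(1))
  s[which.min(p)]
}

# Exact two-sided rank-sum p by exhaustive enumeration of group assignments.
oracle_ranksum_exact <- function(g1, g2) {
  v <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(v), n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mu <- n1 * (length(v) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# A small planted-CNV cohort used by several files.
make_planted_cohort <- function(seed = 101, delta = 0.8, n_planted = 3,
                                noise = 0.15, n_genes = 40, n_snps = 60,
                                coupling = 1.0, model = "qualitative") {
  eff <- data.frame(snp = seq_len(n_planted), gene = seq_len(n_planted),
                    delta = delta, model = model)
  simulate_cohort(simulation_config(
    n_patients = 32, n_genes = n_genes, n_snps = n_snps,
    planted_cnv_effects = eff, cn_noise_sd = noise,
    expr_cn_coupling = coupling, expr_noise_sd = 0.3, seed = seed))
}
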