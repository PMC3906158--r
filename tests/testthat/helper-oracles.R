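# Independent oracles used across the suite. These deliberately use the
# naive dense formulations (explicit n x n covariance, grid/golden-section
# search, full design materialization) so they stay independent of the
# package's Woodbury / closed-form implementation paths.

# penalized per-coordinate objective l(v)
obj_v <- function(v, s, q, lambda) {
  -0.5 * log(1 + v * s) + 0.5 * q^2 * v / (1 + v * s) - lambda * v
}

# 1-D numeric maximizer of l(v) over v >= 0. optimize() cannot localize a
# flat maximum to 1e-8, so the oracle root-finds dl/dv (monotone decreasing
# in v) with Brent's method instead; the derivative is written from the
# objective independently of the package's closed-form quadratic solution.
oracle_vstar <- function(s, q, lambda) {
  dldv <- function(v) -0.5 * s / (1 + v * s) + 0.5 * q^2 / (1 + v * s)^2 - lambda
  if (dldv(0) <= 0) return(0)
  up <- 1
  while (dldv(up) > 0) up <- up * 2
  stats::uniroot(dldv, c(0, up), tol = 1e-14)$root
}

# dense (s, q) factors: build C = sigma2_e I + sum v_l x_l x_l' and invert
oracle_sq <- function(x, X_active, v, sigma2_e, r) {
  n <- length(r)
  C <- diag(sigma2_e, n)
  if (ncol(X_active) > 0) {
    for (l in seq_len(ncol(X_active))) {
      C <- C + v[l] * tcrossprod(X_active[, l])
    }
  }
  Ci <- solve(C)
  list(s = drop(t(x) %*% Ci %*% x), q = drop(t(x) %*% Ci %*% r))
}

# dense Bayesian linear-regression posterior
oracle_posterior <- function(X, v, sigma2_e, r) {
  A <- t(X) %*% X / sigma2_e + diag(1 / v, ncol(X))
  Sigma <- solve(A)
  list(beta_hat = drop(Sigma %*% t(X) %*% r) / sigma2_e, Sigma = Sigma)
}

# small random IMF2-style dataset for solver tests
tiny_dataset <- function(seed, n_chrom = 2, bins_per_chrom = 4, n_ril = 40,
                         n_cross = 25, effects = NULL, sigma2_e = 0.5) {
  cfg <- sim_config(n_chrom = n_chrom, bins_per_chrom = bins_per_chrom,
                    n_ril = n_ril, n_cross = n_cross, seed = seed)
  map <- sim_bin_map(cfg)
  rils <- simulate_rils(cfg, map)
  G <- derive_imf2(rils, n_cross, seed = seed + 1)
  if (is.null(effects)) {
    effects <- data.frame(family = "A", i = 2L, j = 2L, beta = 1)
  }
  truth <- sim_truth(effects, mu = 0, sigma2_e = sigma2_e)
  y <- simulate_phenotype(G, truth, seed = seed + 2)
  list(cfg = cfg, map = map, G = G, truth = truth, y = y)
}

# deterministic small genotype matrix from explicit codes
geno_from <- function(codes_text, bin_ids = NULL) {
  rows <- strsplit(codes_text, "")
  m <- length(rows[[1]])
  codes <- do.call(rbind, rows)
  if (is.null(bin_ids)) bin_ids <- paste0("Bin", seq_len(m))
  geno_matrix(codes, individual_ids = paste0("ind", seq_along(rows)),
              bin_ids = bin_ids)
}
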