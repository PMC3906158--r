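# builds a minimal eblasso_fit-shaped object for testing the reporting layer
fake_fit <- function(beta, sd, X, y, family = NULL, i = NULL, j = NULL) {
  M <- length(beta)
  active <- data.frame(
    family = family %||% rep("A", M),
    i = i %||% seq_len(M), j = j %||% seq_len(M),
    index = seq_len(M), sigma2_j = rep(1, M))
  structure(list(active = active, beta_hat = beta, Sigma = diag(sd^2, M),
                 X_active = X, mu = mean(y), sigma2_e = 1, lambda = 1,
                 prior = prior_spec(0.5, 0.5), n = length(y), m = max(active$j),
                 include_interactions = FALSE),
            class = "eblasso_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("significance_test reproduces the published t quotient", {
  set.seed(1)
  y <- rnorm(278)
  X <- matrix(rnorm(278), ncol = 1)
  fit <- fake_fit(6.79, 0.98, X, y)
  rep_ <- significance_test(fit, y)
  expect_equal(rep_$t, 6.79 / 0.98, tolerance = 1e-12)  # ~6.93
  expect_true(rep_$significant)
  # zero coefficient: t = 0, p = 1, not significant
  fit0 <- fake_fit(0, 0.5, X, y)
  rep0 <- significance_test(fit0, y)
  expect_equal(rep0$t, 0)
  expect_equal(rep0$p_value, 1)
  expect_false(rep0$significant)
})

test_that("t p-value matches numeric integration of the t density", {
  t_obs <- 6.79 / 0.98
  df <- 278 - 1 - 1
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p_quad <- 2 * stats::integrate(dens, t_obs, Inf, rel.tol = 1e-12)$value
  set.seed(1)
  y <- rnorm(278)
  fit <- fake_fit(6.79, 0.98, matrix(rnorm(278)), y)
  expect_equal(significance_test(fit, y)$p_value, p_quad, tolerance = 1e-10)
})

test_that("significance is monotone in alpha and errors without df", {
  set.seed(4)
  y <- rnorm(20)
  M <- 5
  X <- matrix(rnorm(20 * M), 20)
  fit <- fake_fit(seq(0.5, 2.5, length.out = M), rep(0.5, M), X, y)
  for (alphas in list(c(0.1, 0.01), c(0.05, 0.001))) {
    hi <- significance_test(fit, y, alpha = alphas[1])
    lo <- significance_test(fit, y, alpha = alphas[2])
    expect_true(all(which(lo$significant) %in% which(hi$significant)))
  }
  fit_big <- fake_fit(rep(1, 19), rep(0.5, 19), matrix(rnorm(20 * 19), 20), y)
  expect_error(significance_test(fit_big, y), "degrees of freedom")
})

test_that("per_effect_pve follows var(x) beta^2 / var(y)", {
  expect_equal(per_effect_pve(0, rnorm(10), rnorm(10)), 0)
  # var(x) = 0.5, beta = 1, var(y) = 2 -> 0.25
  x <- c(-1, 1) * sqrt(0.5 / 2); x <- rep(x, 50)    # sample var 0.5 (approx)
  set.seed(6)
  for (t_ in 1:20) {
    x <- rnorm(40); y <- rnorm(40, sd = 2); b <- rnorm(1)
    expect_equal(per_effect_pve(b, x, y), stats::var(b * x) / stats::var(y),
                 tolerance = 1e-12)
  }
  expect_warning(p0 <- per_effect_pve(1, rep(1, 10), rnorm(10)), "zero-variance")
  expect_equal(p0, 0)
})

test_that("total_pve_refit: exact fit, orthogonal column, oracle, rank issues", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 3), n)
  beta <- c(1, -2, 0.5)
  y <- drop(X %*% beta) + 3
  expect_equal(total_pve_refit(y, X)$pve, 1.0, tolerance = 1e-12)

  x_orth <- rnorm(n)
  y2 <- rnorm(n)
  expect_lt(total_pve_refit(y2, matrix(x_orth))$pve, 0.2)

  y3 <- drop(X %*% beta) + rnorm(n)
  got <- total_pve_refit(y3, X)
  Xi <- cbind(1, X)
  bh <- solve(t(Xi) %*% Xi, t(Xi) %*% y3)      # normal-equations oracle
  rss <- sum((y3 - Xi %*% bh)^2)
  tss <- sum((y3 - mean(y3))^2)
  expect_equal(got$pve, 1 - rss / tss, tolerance = 1e-10)
  expect_equal(unname(got$coefficients), drop(bh), tolerance = 1e-10)

  # duplicated column is dropped with a warning; PVE unchanged
  Xdup <- cbind(X, X[, 1])
  expect_warning(got_dup <- total_pve_refit(y3, Xdup, p_values = c(1, 2, 3, 4) / 100),
                 "rank-deficient")
  expect_equal(got_dup$pve, got$pve, tolerance = 1e-10)
  expect_equal(got_dup$dropped, 4L)

  expect_equal(total_pve_refit(y3, matrix(numeric(0), n, 0))$pve, 0)
})

test_that("group_qtls chains within a radius and never spans chromosomes", {
  map <- bin_map(paste0("b", 1:6), c("1", "1", "1", "1", "2", "2"),
                 c(0, 15, 32, 60, 0, 25))
  g <- group_qtls(c("b1", "b2", "b3"), map, radius = 20)
  expect_equal(unique(g$group), 1L)            # 0-15-32 chained
  g2 <- group_qtls(c("b5", "b6"), map, radius = 20)
  expect_equal(g2$group, c(1L, 2L))            # 0 vs 25 split
  # same position, different chromosome: separate groups
  g3 <- group_qtls(c("b1", "b5"), map, radius = 20)
  expect_equal(length(unique(g3$group)), 2)
  # input order is irrelevant
  g4 <- group_qtls(c("b3", "b1", "b2"), map, radius = 20)
  expect_equal(g4[order(g4$bin_id), ], g[order(g$bin_id), ], ignore_attr = TRUE)
  expect_error(group_qtls("nope", map), "unknown")
})

test_that("group count equals connected components of the distance graph", {
  set.seed(17)
  m <- 150
  map <- bin_map(paste0("b", 1:m), rep(c("1", "2", "3"), each = 50),
                 rep(sort(runif(50, 0, 400)), 3))
  bins <- sample(map$bin_id, 103)
  g <- group_qtls(bins, map, radius = 20)
  # oracle: igraph connected components of the <= 20 cM graph
  pos <- match(bins, map$bin_id)
  adj <- outer(seq_along(bins), seq_along(bins), function(a, b) {
    map$chrom[pos[a]] == map$chrom[pos[b]] &
      abs(map$pos_cM[pos[a]] - map$pos_cM[pos[b]]) <= 20
  })
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_equal(max(g$group), igraph::components(gr)$no)
})

test_that("associate_genes uses inclusive same-chromosome distances", {
  map <- bin_map(c("b1", "b2"), c("1", "2"), c(10, 10))
  catalog <- data.frame(gene_name = c("g_at", "g_edge", "g_far", "g_chr2"),
                        chrom = c("1", "1", "1", "2"),
                        pos_cM = c(10, 12, 31, 10))
  res <- associate_genes("b1", catalog, map, radius = 20, highlight = 2)
  expect_setequal(res$gene_name, c("g_at", "g_edge"))   # g_far at 21 cM excluded
  expect_true(res$highlighted[res$gene_name == "g_at"])     # distance 0
  expect_true(res$highlighted[res$gene_name == "g_edge"])   # exactly 2.0, inclusive
  expect_false("g_chr2" %in% res$gene_name)                 # same cM, other chrom
  res2 <- associate_genes("b2", catalog, map)
  expect_equal(res2$gene_name, "g_chr2")
})

test_that("effect table round-trips values and metadata", {
  set.seed(23)
  y <- rnorm(50)
  X <- matrix(rnorm(100), 50)
  fit <- fake_fit(c(0.5, -1.2), c(0.1, 0.4), X, y,
                  family = c("A", "AD"), i = c(3, 1), j = c(3, 7))
  rep_ <- significance_test(fit, y)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_effect_table(rep_, f, metadata = list(a = 0.5, b = 0.5, mu = 0.0035,
                                              sigma2_e = 0.1444, total_h2 = 0.9405))
  back <- read_effect_table(f)
  expect_equal(names(back), c("locus_i", "family_i", "locus_j", "family_j",
                              "beta", "sd", "p_value", "h2"))
  expect_equal(back$beta, rep_$beta_hat, tolerance = 1e-12)
  expect_equal(back$family_i, c("add", "add"))
  expect_equal(back$family_j, c("add", "dom"))
  expect_equal(attr(back, "metadata")$total_h2, 0.9405)
  # empty report: header and metadata only
  empty <- rep_[0, ]
  write_effect_table(empty, f, metadata = list(a = 1, b = 1))
  back0 <- read_effect_table(f)
  expect_equal(nrow(back0), 0)
  expect_equal(attr(back0, "metadata")$a, 1)
})

test_that("qtl_report assembles significant effects, groups and genes", {
  ds <- tiny_dataset(61, n_chrom = 2, bins_per_chrom = 10, n_ril = 80,
                     n_cross = 120,
                     effects = data.frame(family = "A", i = 3, j = 3, beta = 1.5),
                     sigma2_e = 0.4)
  fit <- eblasso_fit(ds$G, ds$y, design_spec(ds$G, TRUE), prior_spec(0.5, 0.5))
  catalog <- data.frame(gene_name = "GN1", chrom = "1", pos_cM = 2.5)
  rep_ <- qtl_report(fit, ds$y, ds$map, catalog)
  expect_s3_class(rep_, "qtl_report")
  expect_true(nrow(rep_$significant) >= 1)
  expect_true(rep_$total_h2 >= 0 && rep_$total_h2 <= 1)
  expect_true(all(rep_$significant$p_value <= 0.01))
  if (!is.null(rep_$genes) && nrow(rep_$genes)) {
    expect_true(all(rep_$genes$distance_cM <= 20))
  }
})
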