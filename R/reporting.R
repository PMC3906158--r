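# Post-fit reporting: t-based significance tests from the posterior
# covariance, per-effect and total variance-explained, QTL grouping along
# the map, gene-proximity annotation, and table export.

#' Significance test of active effects
#'
#' t_j = beta_hat_j / sqrt(Sigma_jj) with df = n - M - 1 (M active effects,
#' one df for the intercept), two-sided p-values, flagged at p <= alpha.
#' Per-effect variance explained h2_j = var(x_j) beta_hat_j^2 / var(y) is
#' attached, with var() the sample variance.
#'
#' @param fit an [eblasso_fit()].
#' @param y the phenotype vector the model was fit to.
#' @param alpha significance level (default 0.01, no multiplicity
#'   correction; `bonferroni = TRUE` divides alpha by M).
#' @param use_normal use a standard normal reference instead of Student t
#'   (default FALSE).
#' @param bonferroni logical, default FALSE.
#' @return data frame: family, i, j, index, sigma2_j, beta_hat, sd, t,
#'   p_value, h2, significant.
#' @export
significance_test <- function(fit, y, alpha = 0.01, use_normal = FALSE,
                              bonferroni = FALSE) {
  M <- nrow(fit$active)
  out <- fit$active
  if (M == 0) {
    out$beta_hat <- out$sd <- out$t <- out$p_value <- out$h2 <- numeric(0)
    out$significant <- logical(0)
    return(out)
  }
  df <- fit$n - M - 1
  if (df <= 0) stop("no residual degrees of freedom (n - M - 1 <= 0); reduce the model")
  sd_ <- sqrt(diag(fit$Sigma))
  t_ <- ifelse(fit$beta_hat == 0, 0, fit$beta_hat / sd_)
  p <- if (use_normal) 2 * stats::pnorm(-abs(t_)) else 2 * stats::pt(-abs(t_), df)
  p <- pmin(p, 1)
  vx <- matrixStats_colVar(fit$X_active)
  h2 <- vapply(seq_len(M), function(l) per_effect_pve(fit$beta_hat[l],
                                                      fit$X_active[, l], y),
               numeric(1))
  thr <- if (bonferroni) alpha / M else alpha
  out$beta_hat <- fit$beta_hat
  out$sd <- sd_
  out$t <- t_
  out$p_value <- p
  out$h2 <- h2
  out$significant <- p <= thr
  out
}

#' Per-effect phenotypic variance explained
#'
#' h2_j = var(x_j) beta_hat_j^2 / var(y): the variance of the fitted
#' contribution of one effect over the total phenotypic variance, both as
#' sample variances.
#'
#' @param beta_hat estimated coefficient.
#' @param x design column of the effect.
#' @param y phenotype vector.
#' @return non-negative scalar.
#' @export
per_effect_pve <- function(beta_hat, x, y) {
  vy <- stats::var(y)
  if (vy <= 0) stop("phenotype has zero variance")
  vx <- stats::var(x)
  if (vx == 0) {
    warning("zero-variance design column; h2 = 0")
    return(0)
  }
  vx * beta_hat^2 / vy
}

#' Total variance explained by the significant effects (OLS refit)
#'
#' Refits an ordinary least-squares model with intercept on the significant
#' design columns and reports the coefficient of determination
#' 1 - RSS/TSS. Columns are entered in order of significance (smallest p
#' first); rank-deficient trailing columns are dropped with a warning.
#'
#' @param y phenotype vector.
#' @param X matrix of significant-effect columns (0 columns allowed).
#' @param p_values optional per-column p-values controlling the entry order.
#' @return list: `pve` in [0, 1], `coefficients` (intercept first; dropped
#'   columns NA), `dropped` (column positions in the input ordering).
#' @export
total_pve_refit <- function(y, X, p_values = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = length(X) > 0)
  if (ncol(X) == 0) return(list(pve = 0, coefficients = mean(y), dropped = integer(0)))
  ord <- if (is.null(p_values)) seq_len(ncol(X)) else order(p_values)
  Xo <- X[, ord, drop = FALSE]
  qr_ <- qr(cbind(1, Xo))
  rank_def <- qr_$rank < ncol(Xo) + 1
  keep_cols <- seq_len(ncol(Xo))
  if (rank_def) {
    pivot_kept <- sort(qr_$pivot[seq_len(qr_$rank)])
    keep_cols <- setdiff(pivot_kept, 1) - 1      # design columns kept (in Xo order)
    warning("rank-deficient refit: dropped ", ncol(Xo) - length(keep_cols),
            " collinear column(s)")
    qr_ <- qr(cbind(1, Xo[, keep_cols, drop = FALSE]))
  }
  coef_ <- qr.coef(qr_, y)
  fitted <- qr.fitted(qr_, y)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  full_coef <- rep(NA_real_, ncol(X))
  full_coef[ord[keep_cols]] <- coef_[-1]
  dropped <- setdiff(seq_len(ncol(X)), ord[keep_cols])
  list(pve = max(0, min(1, 1 - rss / tss)),
       coefficients = c(intercept = coef_[1], full_coef),
       dropped = dropped)
}

#' Group QTLs within a cM radius
#'
#' Single-linkage clustering of QTL bins along each chromosome: two bins
#' belong to one group when a chain of member-to-member distances each
#' <= radius connects them. Groups never span chromosomes. Input order is
#' irrelevant (set semantics).
#'
#' @param bins character vector of bin ids (duplicates collapsed).
#' @param map a [bin_map()].
#' @param radius grouping radius in cM (default 20).
#' @return data frame: bin_id, chrom, pos_cM, group (integer id, numbered
#'   along the map).
#' @export
group_qtls <- function(bins, map, radius = 20) {
  bins <- unique(as.character(bins))
  pos <- match(bins, map$bin_id)
  if (anyNA(pos)) stop("unknown bin(s): ", paste(bins[is.na(pos)], collapse = ", "))
  df <- data.frame(bin_id = bins, chrom = map$chrom[pos], pos_cM = map$pos_cM[pos],
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos_cM), , drop = FALSE]
  grp <- integer(nrow(df))
  gid <- 0L
  last_chrom <- NA_character_
  last_pos <- NA_real_
  for (r in seq_len(nrow(df))) {
    new_group <- is.na(last_chrom) || df$chrom[r] != last_chrom ||
      df$pos_cM[r] - last_pos > radius
    if (new_group) gid <- gid + 1L
    grp[r] <- gid
    last_chrom <- df$chrom[r]
    last_pos <- df$pos_cM[r]
  }
  df$group <- grp
  rownames(df) <- NULL
  df
}

#' Associate genes with QTL bins by map proximity
#'
#' For each QTL bin, lists every catalog gene on the same chromosome within
#' `radius` cM (inclusive); associations within `highlight` cM (inclusive)
#' are flagged. Genes on other chromosomes are never associated.
#'
#' @param bins character vector of QTL bin ids.
#' @param catalog gene catalog data frame (gene_name, chrom, pos_cM).
#' @param map a [bin_map()].
#' @param radius association radius in cM (default 20).
#' @param highlight highlight radius in cM (default 2).
#' @return data frame: bin_id, gene_name, distance_cM, highlighted.
#' @export
associate_genes <- function(bins, catalog, map, radius = 20, highlight = 2) {
  bins <- unique(as.character(bins))
  pos <- match(bins, map$bin_id)
  if (anyNA(pos)) stop("unknown bin(s): ", paste(bins[is.na(pos)], collapse = ", "))
  out <- list()
  for (r in seq_along(bins)) {
    same <- catalog$chrom == map$chrom[pos[r]]
    d <- abs(catalog$pos_cM - map$pos_cM[pos[r]])
    sel <- same & d <= radius
    if (any(sel)) {
      out[[length(out) + 1]] <- data.frame(
        bin_id = bins[r], gene_name = catalog$gene_name[sel],
        distance_cM = d[sel], highlighted = d[sel] <= highlight,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(bin_id = character(0), gene_name = character(0),
                      distance_cM = numeric(0), highlighted = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

fam_label <- function(family, which = c("i", "j")) {
  which <- match.arg(which)
  main <- family %in% c("A", "D")
  letter <- ifelse(main, family,
                   substr(family, if (which == "i") 1 else 2,
                          if (which == "i") 1 else 2))
  ifelse(letter == "A", "add", "dom")
}

#' Write / read the effect table
#'
#' TSV with columns locus_i, family_i, locus_j, family_j, beta, sd, p_value,
#' h2 (fixed order), preceded by a "#"-prefixed metadata block carrying a,
#' b, mu, sigma2_e and the total refit h2. `read_effect_table()` round-trips
#' the values and metadata.
#'
#' @param reports output of [significance_test()] (optionally filtered).
#' @param path output file.
#' @param metadata named list (a, b, mu, sigma2_e, total_h2, ...).
#' @return the path, invisibly.
#' @export
write_effect_table <- function(reports, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(metadata)) {
    cat(sprintf("#%s=%.15g\n", nm, as.numeric(metadata[[nm]])), file = con)
  }
  df <- data.frame(
    locus_i = if (nrow(reports)) reports$i else integer(0),
    family_i = fam_label(reports$family, "i"),
    locus_j = if (nrow(reports)) reports$j else integer(0),
    family_j = fam_label(reports$family, "j"),
    beta = reports$beta_hat, sd = reports$sd,
    p_value = reports$p_value, h2 = reports$h2,
    stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}

#' Assemble the full QTL report for one trait
#'
#' Runs the significance test, OLS refit for total variance explained, QTL
#' grouping, and (if a catalog is given) gene association, mirroring the
#' published table layout: per-effect beta_hat (sd), p, h2, plus mu,
#' sigma2_e and the total h2 of the significant set.
#'
#' @param fit an [eblasso_fit()].
#' @param y phenotype vector used for the fit.
#' @param map the [bin_map()] of the genotypes.
#' @param catalog optional gene catalog.
#' @param alpha significance level (default 0.01).
#' @param radius grouping/association radius in cM (default 20).
#' @param highlight gene highlight radius in cM (default 2).
#' @return list of class `qtl_report`: effects (all active), significant,
#'   qtl_bins, groups, genes, total_h2, mu, sigma2_e, prior.
#' @export
qtl_report <- function(fit, y, map, catalog = NULL, alpha = 0.01,
                       radius = 20, highlight = 2) {
  eff <- significance_test(fit, y, alpha = alpha)
  sig <- eff[eff$significant, , drop = FALSE]
  total <- if (nrow(sig)) {
    sel <- match(sig$index, fit$active$index)
    total_pve_refit(y, fit$X_active[, sel, drop = FALSE], sig$p_value)$pve
  } else 0
  qtl_idx <- unique(c(sig$i, sig$j))
  qtl_bins <- map$bin_id[qtl_idx]
  groups <- if (length(qtl_bins)) group_qtls(qtl_bins, map, radius) else NULL
  genes <- if (!is.null(catalog) && length(qtl_bins)) {
    associate_genes(qtl_bins, catalog, map, radius, highlight)
  } else NULL
  structure(list(effects = eff, significant = sig, qtl_bins = qtl_bins,
                 groups = groups, genes = genes, total_h2 = total,
                 mu = fit$mu, sigma2_e = fit$sigma2_e,
                 prior = fit$prior, alpha = alpha),
            class = "qtl_report")
}

#' @export
print.qtl_report <- function(x, ...) {
  cat(sprintf("QTL report: %d significant effect(s) of %d active (p <= %g)\n",
              nrow(x$significant), nrow(x$effects), x$alpha))
  cat(sprintf("  %d QTL bin(s) in %d group(s); total h2 (refit) = %.4f\n",
              length(x$qtl_bins),
              if (is.null(x$groups)) 0 else max(x$groups$group),
              x$total_h2))
  invisible(x)
}
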