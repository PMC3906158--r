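# Synthetic immortalized-F2 (IMF2) population generator and recovery
# scoring. RIL genotypes are two-state Markov chains along the genetic map
# (Haldane map function, selfing map expansion at the F-infinity limit);
# IMF2 crosses combine random distinct RIL pairs; phenotypes come from a
# planted sparse set of main and digenic effects plus Gaussian noise.

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 240 RILs intercrossed into 278
#' IMF2 crosses on a map of ~1.0 cM bins. The desk-scale default genome is
#' 5 chromosomes x 40 bins (m = 200).
#'
#' @param n_chrom number of chromosomes (default 5).
#' @param bins_per_chrom bins per chromosome (default 40).
#' @param cm_per_bin bin spacing in cM (default 1.0).
#' @param n_ril number of recombinant inbred lines (default 240).
#' @param n_cross number of IMF2 crosses (default 278).
#' @param seed integer seed driving all generators.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 5, bins_per_chrom = 40, cm_per_bin = 1.0,
                       n_ril = 240, n_cross = 278, seed = 1) {
  stopifnot(n_chrom >= 1, bins_per_chrom >= 1, cm_per_bin >= 0,
            n_ril >= 2, n_cross >= 1)
  structure(list(n_chrom = n_chrom, bins_per_chrom = bins_per_chrom,
                 cm_per_bin = cm_per_bin, n_ril = n_ril, n_cross = n_cross,
                 seed = seed), class = "sim_config")
}

#' Regular bin map for a simulation
#'
#' Bins are named Bin1..Binm consecutively across chromosomes "1".."n_chrom",
#' spaced `cm_per_bin` cM apart starting at 0 on each chromosome.
#'
#' @param cfg a [sim_config()].
#' @return a [bin_map()].
#' @export
sim_bin_map <- function(cfg) {
  m <- cfg$n_chrom * cfg$bins_per_chrom
  bin_map(paste0("Bin", seq_len(m)),
          rep(as.character(seq_len(cfg$n_chrom)), each = cfg$bins_per_chrom),
          rep(cfg$cm_per_bin * (seq_len(cfg$bins_per_chrom) - 1), cfg$n_chrom))
}

#' Haldane map function
#'
#' Converts a genetic distance in cM to a recombination fraction assuming no
#' crossover interference: r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM distance in centi-Morgan, >= 0.
#' @return recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("negative map distance")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' RIL genotype switch probability
#'
#' Map expansion for recombinant inbred lines by repeated selfing at the
#' F-infinity limit: the probability that adjacent bins carry different
#' parental genotypes is R = 2r / (1 + 2r).
#'
#' @param r per-meiosis recombination fraction in [0, 0.5].
#' @return switch probability in [0, 0.5].
#' @export
ril_switch_prob <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("recombination fraction outside [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Simulate fully homozygous RIL genotypes
#'
#' Each RIL chromosome is a two-state {A, B} Markov chain: the first bin is
#' A or B with probability 1/2 and each subsequent bin switches parent with
#' probability [ril_switch_prob()] of the adjacent-bin Haldane fraction.
#'
#' @param cfg a [sim_config()].
#' @param map bin map (default [sim_bin_map()] of `cfg`).
#' @return a [geno_matrix()] over {A, B} with `cfg$n_ril` rows.
#' @export
simulate_rils <- function(cfg, map = sim_bin_map(cfg)) {
  n <- cfg$n_ril
  m <- nrow(map)
  with_local_seed(cfg$seed, {
    out <- matrix(0L, n, m)   # 0 = A, 1 = B
    for (ch in unique(map$chrom)) {
      cols <- which(map$chrom == ch)
      state <- stats::rbinom(n, 1, 0.5)
      out[, cols[1]] <- state
      if (length(cols) > 1) {
        d <- diff(map$pos_cM[cols])
        R <- ril_switch_prob(haldane_r(d))
        for (l in seq_along(d)) {
          flip <- stats::runif(n) < R[l]
          state <- ifelse(flip, 1L - state, state)
          out[, cols[l + 1]] <- state
        }
      }
    }
    codes <- matrix(c("A", "B")[out + 1L], n, m)
    rownames(codes) <- sprintf("RIL%03d", seq_len(n))
    colnames(codes) <- map$bin_id
    geno_matrix(codes)
  })
}

#' Derive IMF2 genotypes from RIL parents
#'
#' Samples `n_cross` distinct unordered RIL pairs (without replacement of
#' pairs) and combines parental genotypes per bin: identical homozygotes
#' stay, differing parents give the heterozygote H.
#'
#' @param rils homozygous [geno_matrix()] over {A, B}.
#' @param n_cross number of crosses.
#' @param seed integer seed.
#' @return a [geno_matrix()] over {A, H, B} with attribute `parents`
#'   (two-column matrix of RIL row indices).
#' @export
derive_imf2 <- function(rils, n_cross, seed = 1) {
  n_ril <- nrow(rils)
  if (any(unclass(rils) == "H")) stop("RIL parents must be homozygous")
  npairs <- n_ril * (n_ril - 1) / 2
  if (n_cross > npairs) stop("n_cross exceeds the ", npairs, " available distinct pairs")
  pair_idx <- with_local_seed(seed, sample(npairs, n_cross))
  pr <- pair_from_index(pair_idx, n_ril)
  G1 <- unclass(rils)[pr$i, , drop = FALSE]
  G2 <- unclass(rils)[pr$j, , drop = FALSE]
  codes <- matrix("H", n_cross, ncol(rils))
  same <- G1 == G2
  codes[same] <- G1[same]
  rownames(codes) <- sprintf("IMF2_%03d", seq_len(n_cross))
  colnames(codes) <- colnames(rils)
  out <- geno_matrix(codes)
  attr(out, "parents") <- cbind(pr$i, pr$j)
  out
}

#' Planted ground truth
#'
#' @param effects data frame with columns family, i, j, beta (descriptors
#'   valid for the map; i < j for interactions).
#' @param mu population mean.
#' @param sigma2_e residual variance.
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(effects, mu = 0, sigma2_e = 1) {
  stopifnot(all(c("family", "i", "j", "beta") %in% names(effects)),
            sigma2_e >= 0)
  for (r in seq_len(nrow(effects))) {       # validates family/i/j constraints
    effect_descriptor(effects$family[r], effects$i[r], effects$j[r])
  }
  structure(list(effects = effects, mu = mu, sigma2_e = sigma2_e),
            class = "sim_truth")
}

#' Default planted architecture: 2 main + 4 digenic effects, h2 ~ 0.6
#'
#' Plants one additive and one dominance main effect and one interaction of
#' each family (AA, AD, DA, DD) at fixed relative map positions, with
#' |beta| between 1.2 and 1.5 (at least half a phenotypic standard
#' deviation). The ten involved loci are mutually separated by at least
#' 25 cM (or sit on different chromosomes) under the default 5 x 40-bin
#' map, so planted effects are identifiable as distinct QTLs; closely
#' linked dominance effects would otherwise be absorbed by composite
#' surrogate columns (see the package vignette). The residual variance is
#' set from the realized genetic variance so that the total heritability
#' is approximately `target_h2`.
#'
#' @param G the simulated genotype matrix the phenotype will be built on.
#' @param target_h2 total heritability target (default 0.6).
#' @param mu population mean (default 0).
#' @return a [sim_truth()].
#' @export
default_sim_truth <- function(G, target_h2 = 0.6, mu = 0) {
  m <- ncol(G)
  at <- function(f) max(1, round(f * m))
  effects <- data.frame(
    family = c("A", "D", "AA", "AD", "DA", "DD"),
    i = c(at(0.025), at(0.225), at(0.175), at(0.375), at(0.425), at(0.625)),
    j = c(at(0.025), at(0.225), at(0.575), at(0.825), at(0.975), at(0.775)),
    beta = c(1.2, 1.5, 1.2, 1.2, -1.2, 1.5),
    stringsAsFactors = FALSE)
  g <- genetic_values(G, effects)
  vg <- stats::var(g)
  sigma2_e <- vg * (1 - target_h2) / target_h2
  sim_truth(effects, mu = mu, sigma2_e = sigma2_e)
}

genetic_values <- function(G, effects) {
  g <- numeric(nrow(G))
  for (r in seq_len(nrow(effects))) {
    d <- list(family = effects$family[r], i = effects$i[r], j = effects$j[r])
    g <- g + effects$beta[r] * effect_column(d, G)
  }
  g
}

#' Simulate phenotypes from planted effects
#'
#' y = mu + sum_effects x_effect * beta + e, e ~ N(0, sigma2_e).
#'
#' @param G a [geno_matrix()].
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @return named numeric phenotype vector with attribute `genetic_values`.
#' @export
simulate_phenotype <- function(G, truth, seed = 1) {
  g <- genetic_values(G, truth$effects)
  e <- with_local_seed(seed, stats::rnorm(nrow(G), 0, sqrt(truth$sigma2_e)))
  y <- truth$mu + g + e
  names(y) <- rownames(G)
  attr(y, "genetic_values") <- g
  y
}

#' Score recovery of planted effects
#'
#' A true effect is HIT when some significant reported effect of the same
#' class (main vs interaction) places every involved bin within `tol_cM`
#' (same chromosome) of the corresponding true bin; interaction pairs are
#' matched in the better of the two orientations. Power = hits / number of
#' true effects; FDR = significant reports matching no true effect / total
#' significant reports (0 with `fdr_defined = FALSE` when nothing was
#' reported).
#'
#' @param reports data frame with columns family, i, j (significant effects,
#'   e.g. the `significant` element of [qtl_report()]).
#' @param truth a [sim_truth()].
#' @param map the [bin_map()] both refer to.
#' @param tol_cM mapping tolerance in cM (default 5).
#' @return list: power, fdr, fdr_defined, hits (logical per true effect),
#'   matched (logical per reported effect), n_sig.
#' @export
score_recovery <- function(reports, truth, map, tol_cM = 5) {
  n_true <- nrow(truth$effects)
  n_rep <- nrow(reports)
  bin_close <- function(i1, i2) {
    map$chrom[i1] == map$chrom[i2] &
      abs(map$pos_cM[i1] - map$pos_cM[i2]) <= tol_cM
  }
  hits <- logical(n_true)
  matched <- logical(n_rep)
  if (n_rep > 0) {
    rep_main <- reports$family %in% c("A", "D")
    for (t_ in seq_len(n_true)) {
      tf <- truth$effects$family[t_]
      ti <- truth$effects$i[t_]; tj <- truth$effects$j[t_]
      if (tf %in% c("A", "D")) {
        ok <- rep_main & bin_close(reports$i, ti)
      } else {
        straight <- bin_close(reports$i, ti) & bin_close(reports$j, tj)
        flipped <- bin_close(reports$i, tj) & bin_close(reports$j, ti)
        ok <- !rep_main & (straight | flipped)
      }
      if (any(ok)) {
        hits[t_] <- TRUE
        matched <- matched | ok
      }
    }
  }
  power <- if (n_true) mean(hits) else NA_real_
  fdr_defined <- n_rep > 0
  fdr <- if (fdr_defined) mean(!matched) else 0
  list(power = power, fdr = fdr, fdr_defined = fdr_defined,
       hits = hits, matched = matched, n_sig = n_rep)
}

#' One-call synthetic IMF2 dataset
#'
#' Convenience wrapper: map, RILs, IMF2 crosses, planted truth and
#' phenotype, all driven by `cfg$seed` (sub-seeds are derived
#' deterministically).
#'
#' @param cfg a [sim_config()].
#' @param truth optional [sim_truth()]; default [default_sim_truth()].
#' @param target_h2 heritability target when `truth` is NULL.
#' @return list: map, rils, G (IMF2 genotypes), truth, y.
#' @export
simulate_imf2_dataset <- function(cfg = sim_config(), truth = NULL,
                                  target_h2 = 0.6) {
  map <- sim_bin_map(cfg)
  rils <- simulate_rils(cfg, map)
  G <- derive_imf2(rils, cfg$n_cross, seed = cfg$seed + 1000L)
  if (is.null(truth)) truth <- default_sim_truth(G, target_h2 = target_h2)
  y <- simulate_phenotype(G, truth, seed = cfg$seed + 2000L)
  list(map = map, rils = rils, G = G, truth = truth, y = y)
}
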