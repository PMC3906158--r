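# Numeric genotype coding and the six-block effect index space
# [A main | D main | AA | AD | DA | DD]; interaction pairs (i, j), i < j,
# enumerated lexicographically. The full design matrix (k columns, k up to
# millions) is never stored: columns are materialized blockwise on demand.

EFFECT_FAMILIES <- c("A", "D", "AA", "AD", "DA", "DD")

#' Additive genotype coding
#'
#' Maps parental homozygotes and the heterozygote to the additive scale:
#' A -> +1, H -> 0, B -> -1.
#'
#' @param code character vector over {A,H,B}.
#' @return integer vector in {+1, 0, -1}.
#' @export
code_additive <- function(code) {
  v <- c(A = 1L, H = 0L, B = -1L)[code]
  if (anyNA(v)) stop("invalid genotype code")
  unname(v)
}

#' Dominance genotype coding
#'
#' A -> 0, H -> +1, B -> 0; equivalently 1 - additive^2 on this alphabet.
#'
#' @param code character vector over {A,H,B}.
#' @return integer vector in {0, +1}.
#' @export
code_dominance <- function(code) {
  v <- c(A = 0L, H = 1L, B = 0L)[code]
  if (anyNA(v)) stop("invalid genotype code")
  unname(v)
}

#' Effect descriptor
#'
#' Identifies one candidate effect: a family among A/D (main effects) and
#' AA/AD/DA/DD (digenic interactions) and the 1-based bin indices involved.
#' Main effects have `i == j`; interactions require `i < j`.
#'
#' @param family one of "A","D","AA","AD","DA","DD".
#' @param i,j 1-based bin indices.
#' @return list with class `effect_descriptor`.
#' @export
effect_descriptor <- function(family, i, j = i) {
  family <- match.arg(family, EFFECT_FAMILIES)
  i <- as.integer(i); j <- as.integer(j)
  if (family %in% c("A", "D")) {
    if (i != j) stop("main effect requires i == j")
  } else if (i >= j) {
    stop("interaction requires i < j")
  }
  structure(list(family = family, i = i, j = j), class = "effect_descriptor")
}

#' @export
format.effect_descriptor <- function(x, ...) {
  if (x$family %in% c("A", "D")) {
    sprintf("Bin%d_%s", x$i, if (x$family == "A") "add" else "dom")
  } else {
    fam <- strsplit(x$family, "")[[1]]
    sprintf("Bin%d_%s x Bin%d_%s", x$i,
            if (fam[1] == "A") "add" else "dom",
            x$j, if (fam[2] == "A") "add" else "dom")
  }
}

#' @export
print.effect_descriptor <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Total number of candidate effect variables
#'
#' With interactions, k = 2m + 4q with q = m(m-1)/2 (additive and dominance
#' main effects for each of m bins, plus the four interaction families over
#' all unordered bin pairs); main-effects-only gives k = 2m.
#'
#' @param m number of marker bins (>= 1).
#' @param include_interactions logical.
#' @return integer-valued count (double, to hold counts above 2^31).
#' @examples
#' num_variables(1619, TRUE)   # 5242322
#' num_variables(1619, FALSE)  # 3238
#' @export
num_variables <- function(m, include_interactions = TRUE) {
  m <- as.numeric(m)
  if (m < 1) stop("m must be >= 1")
  if (include_interactions) 2 * m + 4 * m * (m - 1) / 2 else 2 * m
}

#' Design specification
#'
#' Describes the candidate-effect space for a genotype matrix: marker count,
#' whether interactions are included, total column count k under the fixed
#' layout, and the eagerly known excluded columns (main-effect columns of
#' monomorphic or constant bins). Zero-variance interaction columns are
#' detected and dropped lazily during block streaming.
#'
#' @param G a [geno_matrix()].
#' @param include_interactions logical (default TRUE).
#' @return list with class `design_spec`: m, include_interactions, k,
#'   excluded (sorted integer vector of linear column indices).
#' @export
design_spec <- function(G, include_interactions = TRUE) {
  m <- ncol(G)
  XA <- code_matrix(G, "A")
  XD <- code_matrix(G, "D")
  excl <- c(which(matrixStats_colVar(XA) == 0),          # A main block
            m + which(matrixStats_colVar(XD) == 0))      # D main block
  structure(list(m = m, include_interactions = include_interactions,
                 k = num_variables(m, include_interactions),
                 excluded = sort(unique(as.numeric(excl)))),
            class = "design_spec")
}

# per-column sample variance of a numeric matrix (no extra deps)
matrixStats_colVar <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

code_matrix <- function(G, family = c("A", "D")) {
  family <- match.arg(family)
  codes <- unclass(G)
  X <- if (family == "A") {
    matrix(code_additive(codes), nrow(codes), ncol(codes))
  } else {
    matrix(code_dominance(codes), nrow(codes), ncol(codes))
  }
  storage.mode(X) <- "double"
  dimnames(X) <- dimnames(codes)
  X
}

#' Map linear column indices to effect descriptors (vectorized internals)
#'
#' The fixed layout is `[A main (m) | D main (m) | AA (q) | AD (q) | DA (q) |
#' DD (q)]`, with interaction pairs enumerated lexicographically by (i, j),
#' i < j. Indices are 1-based: idx 1 is the additive main effect of bin 1.
#'
#' @param idx vector of linear indices in [1, k].
#' @param m marker count.
#' @param include_interactions logical.
#' @return data frame with columns family, i, j.
#' @export
index_to_descriptor <- function(idx, m, include_interactions = TRUE) {
  idx <- as.numeric(idx)
  k <- num_variables(m, include_interactions)
  if (any(idx < 1 | idx > k)) stop("index out of range [1, ", k, "]")
  q <- m * (m - 1) / 2
  fam <- character(length(idx)); i <- numeric(length(idx)); j <- numeric(length(idx))
  main <- idx <= 2 * m
  fam[main] <- ifelse(idx[main] <= m, "A", "D")
  i[main] <- ifelse(idx[main] <= m, idx[main], idx[main] - m)
  j[main] <- i[main]
  if (any(!main)) {
    rest <- idx[!main] - 2 * m
    block <- floor((rest - 1) / q)          # 0..3 -> AA, AD, DA, DD
    p <- rest - block * q                   # pair index 1..q
    ij <- pair_from_index(p, m)
    fam[!main] <- c("AA", "AD", "DA", "DD")[block + 1]
    i[!main] <- ij$i
    j[!main] <- ij$j
  }
  data.frame(family = fam, i = as.integer(i), j = as.integer(j),
             stringsAsFactors = FALSE)
}

#' @rdname index_to_descriptor
#' @param family,i,j vectors describing effects (as in [effect_descriptor()]).
#' @export
descriptor_to_index <- function(family, i, j, m, include_interactions = TRUE) {
  q <- m * (m - 1) / 2
  i <- as.numeric(i); j <- as.numeric(j)
  block <- match(family, EFFECT_FAMILIES)
  if (anyNA(block)) stop("unknown family")
  main <- block <= 2
  if (any(i[main] != j[main])) stop("main effect requires i == j")
  if (any(i[!main] >= j[!main])) stop("interaction requires i < j")
  if (any(i < 1 | j > m)) stop("bin index out of range")
  idx <- numeric(length(block))
  idx[main] <- (block[main] - 1) * m + i[main]
  if (any(!main)) {
    p <- pair_to_index(i[!main], j[!main], m)
    idx[!main] <- 2 * m + (block[!main] - 3) * q + p
  }
  if (include_interactions) idx else {
    if (any(!main)) stop("interaction index requested under main-effects-only layout")
    idx
  }
}

# pair (i, j), i < j, <-> lexicographic rank p in 1..m(m-1)/2
pair_to_index <- function(i, j, m) {
  (i - 1) * m - i * (i - 1) / 2 + (j - i)
}

pair_from_index <- function(p, m) {
  # cumulative pairs after finishing row i: C_i = i*m - i(i+1)/2
  cum <- cumsum(seq(m - 1, 1))
  i <- findInterval(p - 1e-9, c(0, cum))   # row whose range contains p
  before <- c(0, cum)[i]
  j <- i + (p - before)
  list(i = as.integer(i), j = as.integer(j))
}

#' Materialize one effect column
#'
#' Main families return the coded marker column; interaction families return
#' the element-wise product of the two coded main-effect columns.
#'
#' @param desc an [effect_descriptor()] (or list with family, i, j).
#' @param G a [geno_matrix()].
#' @return numeric vector of length n.
#' @export
effect_column <- function(desc, G) {
  XA <- code_matrix(G, "A")
  XD <- code_matrix(G, "D")
  fam <- desc$family
  if (!fam %in% EFFECT_FAMILIES) stop("unknown family")
  if (!fam %in% c("A", "D") && desc$i >= desc$j) stop("interaction requires i < j")
  switch(fam,
         A = XA[, desc$i],
         D = XD[, desc$i],
         AA = XA[, desc$i] * XA[, desc$j],
         AD = XA[, desc$i] * XD[, desc$j],
         DA = XD[, desc$i] * XA[, desc$j],
         DD = XD[, desc$i] * XD[, desc$j])
}

# Materialize the columns at linear indices `idx` from precoded XA/XD.
# Used by the block streamer and the solver; vectorized over idx.
materialize_columns <- function(idx, XA, XD, m, include_interactions = TRUE) {
  d <- index_to_descriptor(idx, m, include_interactions)
  n <- nrow(XA)
  out <- matrix(0, n, length(idx))
  for (fam in unique(d$family)) {
    sel <- d$family == fam
    out[, sel] <- switch(fam,
      A = XA[, d$i[sel], drop = FALSE],
      D = XD[, d$i[sel], drop = FALSE],
      AA = XA[, d$i[sel], drop = FALSE] * XA[, d$j[sel], drop = FALSE],
      AD = XA[, d$i[sel], drop = FALSE] * XD[, d$j[sel], drop = FALSE],
      DA = XD[, d$i[sel], drop = FALSE] * XA[, d$j[sel], drop = FALSE],
      DD = XD[, d$i[sel], drop = FALSE] * XD[, d$j[sel], drop = FALSE])
  }
  out
}

#' Stream design columns in blocks
#'
#' Yields every non-excluded candidate column exactly once, in layout order,
#' as (indices, n x block matrix) chunks; memory stays O(n * block_size).
#' Columns with zero sample variance (monomorphic bins, empty interaction
#' products) are dropped from the stream.
#'
#' @param G a [geno_matrix()].
#' @param spec a [design_spec()].
#' @param block_size number of columns per chunk (>= 1).
#' @param callback function(idx, X) called for each chunk; `idx` are the
#'   surviving linear indices, `X` the corresponding columns.
#' @return invisibly, the total number of streamed columns.
#' @export
column_blocks <- function(G, spec, block_size, callback) {
  stopifnot(block_size >= 1)
  XA <- code_matrix(G, "A")
  XD <- code_matrix(G, "D")
  total <- 0L
  k <- spec$k
  start <- 1
  while (start <= k) {
    stop_ <- min(start + block_size - 1, k)
    idx <- seq(start, stop_)
    idx <- setdiff(idx, spec$excluded)
    if (length(idx)) {
      X <- materialize_columns(idx, XA, XD, spec$m, spec$include_interactions)
      keep <- matrixStats_colVar(X) > 0
      if (any(keep)) {
        callback(idx[keep], X[, keep, drop = FALSE])
        total <- total + sum(keep)
      }
    }
    start <- stop_ + 1
  }
  invisible(total)
}

#' Dense design matrix (testing aid, small m only)
#'
#' Builds the full candidate matrix directly from the definitions. Refuses
#' m > 100.
#'
#' @inheritParams column_blocks
#' @param drop_excluded drop zero-variance columns (default FALSE: the raw
#'   layout, for oracle comparisons).
#' @return numeric matrix with k (or fewer) columns; attribute `indices`
#'   holds the linear index of each column.
#' @export
dense_design <- function(G, include_interactions = TRUE, drop_excluded = FALSE) {
  m <- ncol(G)
  if (m > 100) stop("dense_design is a testing aid; m must be <= 100")
  XA <- code_matrix(G, "A")
  XD <- code_matrix(G, "D")
  k <- num_variables(m, include_interactions)
  X <- materialize_columns(seq_len(k), XA, XD, m, include_interactions)
  idx <- seq_len(k)
  if (drop_excluded) {
    keep <- matrixStats_colVar(X) > 0
    X <- X[, keep, drop = FALSE]
    idx <- idx[keep]
  }
  attr(X, "indices") <- idx
  X
}
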