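# Hyperparameter selection: five-fold cross-validation over (a, b) in three
# steps, minimizing the prediction error, with a one-standard-error early
# stop along the step-2 and step-3 grids.

#' Prediction error
#'
#' Sum of squared residuals between observed and predicted phenotypes.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return sum((y_true - y_pred)^2).
#' @export
prediction_error <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sum((y_true - y_pred)^2)
}

#' Seed-reproducible k-fold assignment
#'
#' Random partition of 1..n into k folds of size floor(n/k) or ceiling(n/k).
#' Uses a private RNG stream; the global RNG state is untouched.
#'
#' @param n number of individuals (>= k).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of length n with fold labels in 1..k.
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  if (n < k) stop("n must be >= k")
  perm <- with_local_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), length.out = n)
  folds
}

# evaluate thunk under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cross-validation grids of the three selection steps
#'
#' Step 1 examines the four diagonal pairs a = b in {0.001, 0.01, 0.1, 1}.
#' Step 2 fixes b at the step-1 winner and scans 15 values of a from -0.9 up
#' to 1. Step 3 fixes a at the step-2 winner and scans b from 0.01 to 10:
#' decade steps below 1 and unit steps above, i.e. {0.01, 0.1, 1, 2, ..., 10}
#' (12 values).
#'
#' @return list with `step1` (data frame a, b), `step2_a` (numeric, 15
#'   values), `step3_b` (numeric, 12 values).
#' @export
cv_step_grids <- function() {
  list(
    step1 = data.frame(a = c(0.001, 0.01, 0.1, 1), b = c(0.001, 0.01, 0.1, 1)),
    step2_a = c(-0.9, -0.8, -0.7, -0.6, -0.5, -0.4, -0.3, -0.2, -0.1,
                -0.01, 0.01, 0.05, 0.1, 0.5, 1),
    step3_b = c(0.01, 0.1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  )
}

cv_eval_pair <- function(G, y, a, b, folds, include_interactions, controls) {
  k <- max(folds)
  pe <- vapply(seq_len(k), function(f) {
    train <- folds != f
    Gtr <- subset_geno(G, train)
    fit <- eblasso_fit(Gtr, y[train], design_spec(Gtr, include_interactions),
                       prior_spec(a, b), controls)
    prediction_error(y[!train], predict(fit, subset_geno(G, !train)))
  }, numeric(1))
  pe
}

subset_geno <- function(G, rows) {
  geno_matrix(unclass(G)[rows, , drop = FALSE])
}

#' Three-step five-fold cross-validation for (a, b)
#'
#' Executes the three steps of [cv_step_grids()] in order on a shared fold
#' assignment. Within steps 2 and 3 the grid is traversed in ascending order
#' and evaluation stops early once the current mean PE exceeds the smallest
#' mean PE seen so far by more than one standard error of that minimum
#' (`one_se = FALSE` disables the stop and evaluates full grids). The
#' returned best pair minimizes mean PE over all evaluated pairs; ties break
#' toward stronger shrinkage (larger b, then larger a).
#'
#' @param G a [geno_matrix()].
#' @param y phenotype vector.
#' @param include_interactions logical; FALSE gives the main-effect model.
#' @param controls an [eblasso_controls()] passed to every fold fit.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param one_se apply the one-standard-error early stop (default TRUE).
#' @return A `cv_result`: `table` (step, a, b, PE_mean, PE_se, PE per fold),
#'   `best` (list a, b), `folds`, `step_log`.
#' @export
cv_path <- function(G, y, include_interactions = TRUE,
                    controls = eblasso_controls(), k = 5, seed = 1,
                    one_se = TRUE) {
  grids <- cv_step_grids()
  folds <- kfold_split(nrow(G), k, seed)
  rows <- list()
  log_ <- character(0)

  eval_pair <- function(step, a, b) {
    pe <- cv_eval_pair(G, y, a, b, folds, include_interactions, controls)
    row <- data.frame(step = step, a = a, b = b,
                      PE_mean = mean(pe), PE_se = stats::sd(pe) / sqrt(length(pe)))
    for (f in seq_along(pe)) row[[paste0("PE", f)]] <- pe[f]
    rows[[length(rows) + 1]] <<- row
    row
  }
  best_so_far <- function() {
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$PE_mean, -tab$b, -tab$a), ]
    tab[1, ]
  }

  # step 1: diagonal pairs, always fully evaluated
  for (r in seq_len(nrow(grids$step1))) {
    eval_pair(1L, grids$step1$a[r], grids$step1$b[r])
  }
  b1 <- best_so_far()$b
  log_ <- c(log_, sprintf("step 1: b1 = %g (PE = %g)", b1, best_so_far()$PE_mean))

  # step 2: scan a at fixed b1, ascending, 1-SE early stop
  for (a in grids$step2_a) {
    row <- eval_pair(2L, a, b1)
    bst <- best_so_far()
    if (one_se && row$PE_mean > bst$PE_mean + bst$PE_se) {
      log_ <- c(log_, sprintf("step 2: stopped after a = %g (1-SE rule)", a))
      break
    }
  }
  a2 <- best_so_far()$a
  log_ <- c(log_, sprintf("step 2: a2 = %g", a2))

  # step 3: scan b at fixed a2, ascending, 1-SE early stop
  for (b in grids$step3_b) {
    row <- eval_pair(3L, a2, b)
    bst <- best_so_far()
    if (one_se && row$PE_mean > bst$PE_mean + bst$PE_se) {
      log_ <- c(log_, sprintf("step 3: stopped after b = %g (1-SE rule)", b))
      break
    }
  }
  bst <- best_so_far()
  log_ <- c(log_, sprintf("best (a, b) = (%g, %g), PE = %g", bst$a, bst$b, bst$PE_mean))

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, best = list(a = bst$a, b = bst$b),
                 folds = folds, step_log = log_),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Three-step five-fold CV:", nrow(x$table), "pairs evaluated\n")
  for (l in x$step_log) cat(" ", l, "\n")
  invisible(x)
}
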