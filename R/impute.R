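# Iterative random-forest imputation of missing trait values.

#' Impute missing trait values
#'
#' Fills missing cells of an individual-level trait table with an iterative
#' random-forest scheme in the missForest style: missing cells are
#' initialized with per-trait medians, then the procedure cycles over trait
#' columns (in order of increasing missingness), fits a random forest of
#' each trait on all other traits plus the plot and species labels, and
#' re-predicts the missing cells, until the relative change of the imputed
#' values falls below `tol` or `max_iter` is reached. Plot and species
#' enter as categorical predictors, so the imputation borrows strength from
#' conspecifics and from co-occurring individuals.
#'
#' Observed cells are never modified, and imputed values are clamped to the
#' observed range of their trait column.
#'
#' @param trait_table data frame with `species` and `plot` columns plus the
#'   canonical trait columns (see [trait_names()]), possibly with `NA`
#'   cells.
#' @param max_iter maximum number of sweeps over the trait columns.
#' @param tol convergence threshold on the relative (Frobenius) change of
#'   the vector of imputed cells between sweeps.
#' @param seed integer seed controlling the forests; fixed seed gives a
#'   deterministic result.
#' @param num_trees trees per forest.
#' @return An object of class `trait_imputation`: list with `data` (the
#'   completed trait table), `mask` (logical matrix of imputed cells),
#'   `iterations`, `converged`, and `delta` (relative change per sweep).
#' @examples
#' com <- generate_community(synthetic_config(n_plots = 2,
#'   individuals_per_plot = 100, seed = 3))
#' imp <- impute_traits(com$trait_table, seed = 3)
#' imp$converged
#' @export
impute_traits <- function(trait_table, max_iter = 10L, tol = 1e-3,
                          seed = 1L, num_trees = 100L) {
  tr <- intersect(trait_names(), names(trait_table))
  if (length(tr) < 2L) stop("trait_table must contain at least two trait columns")
  if (!all(c("species", "plot") %in% names(trait_table))) {
    stop("trait_table must contain 'species' and 'plot' columns")
  }
  X <- as.matrix(trait_table[, tr, drop = FALSE])
  miss <- is.na(X)
  fully_missing <- colnames(X)[colSums(!miss) == 0L]
  if (length(fully_missing)) {
    stop("trait column(s) entirely missing: ",
         paste(fully_missing, collapse = ", "))
  }
  out <- trait_table
  if (!any(miss)) {
    res <- list(data = out, mask = miss, iterations = 0L,
                converged = TRUE, delta = numeric(0))
    class(res) <- "trait_imputation"
    return(res)
  }

  # median initialization
  for (j in seq_len(ncol(X))) {
    X[miss[, j], j] <- stats::median(X[!miss[, j], j])
  }
  rng <- apply(as.matrix(trait_table[, tr, drop = FALSE]), 2,
               range, na.rm = TRUE)

  fac <- data.frame(plot = factor(trait_table$plot),
                    species = factor(trait_table$species))
  ord <- order(colSums(miss))          # least missing first
  deltas <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    old_imp <- X[miss]
    for (j in ord) {
      mj <- miss[, j]
      if (!any(mj)) next
      df <- cbind(as.data.frame(X[, -j, drop = FALSE]), fac)
      df$.y <- X[, j]
      fit <- ranger::ranger(
        dependent.variable.name = ".y",
        data = df[!mj, , drop = FALSE],
        num.trees = num_trees,
        respect.unordered.factors = "order",
        seed = as.integer(seed) + j,
        num.threads = 1L
      )
      pred <- stats::predict(fit, data = df[mj, , drop = FALSE],
                             num.threads = 1L)$predictions
      X[mj, j] <- pmin(pmax(pred, rng[1, j]), rng[2, j])
    }
    delta <- sqrt(sum((X[miss] - old_imp)^2)) /
      max(sqrt(sum(X[miss]^2)), .Machine$double.eps)
    deltas <- c(deltas, delta)
    if (delta < tol) { converged <- TRUE; break }
    # standard iterative-RF stopping rule: once the update stops
    # shrinking, further sweeps only resample forest noise
    if (it >= 2L && delta >= deltas[it - 1L]) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("imputation did not converge in ", max_iter,
            " sweeps (last relative change ", signif(deltas[length(deltas)], 3),
            "); returning last iterate")
  }
  out[, tr] <- as.data.frame(X)
  res <- list(data = out, mask = miss, iterations = it,
              converged = converged, delta = deltas)
  class(res) <- "trait_imputation"
  res
}

#' @export
print.trait_imputation <- function(x, ...) {
  cat("Trait imputation\n")
  cat(sprintf("  imputed cells: %d (%.2f%% of table)\n", sum(x$mask),
              100 * mean(x$mask)))
  cat(sprintf("  sweeps: %d, converged: %s\n", x$iterations, x$converged))
  invisible(x)
}

#' Score imputation accuracy against known masked values
#'
#' Convenience for mask-and-recover experiments: correlates imputed values
#' with the true values at masked cells and tests the association.
#'
#' @param imputation a [impute_traits()] result.
#' @param truth_table the complete (pre-masking) trait table.
#' @param scale correlate on the analysis scale (log where appropriate) so
#'   heavy-tailed traits do not dominate.
#' @return list with `r` (Pearson correlation), `p_value`, and `n` cells.
#' @export
score_imputation <- function(imputation, truth_table, scale = TRUE) {
  tr <- colnames(imputation$mask)
  Ximp <- as.matrix(imputation$data[, tr, drop = FALSE])
  Xtru <- as.matrix(truth_table[, tr, drop = FALSE])
  if (scale) {
    ref <- trait_reference()
    lg <- ref$log_scale[match(tr, ref$trait)]
    Ximp[, lg] <- log(Ximp[, lg])
    Xtru[, lg] <- log(Xtru[, lg])
    Ximp <- scale(Ximp); Xtru <- scale(Xtru)
  }
  imp <- Ximp[imputation$mask]
  tru <- Xtru[imputation$mask]
  ct <- stats::cor.test(imp, tru)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(imp))
}
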