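# Two-dimensional functional trait space: individual-level PCA with
# varimax rotation of the two leading axes.

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the variance of squared loadings per
#' axis, with Kaiser row normalization. This is the rotation step used by
#' [fit_trait_space()].
#'
#' @param loadings p x k loading matrix.
#' @param eps convergence tolerance of the rotation sweeps.
#' @return list with `loadings` (rotated matrix) and `rotmat` (k x k
#'   orthogonal rotation matrix, `loadings_in %*% rotmat = loadings`).
#' @export
varimax_rotation <- function(loadings, eps = 1e-14) {
  vm <- stats::varimax(loadings, normalize = TRUE, eps = eps)
  R <- vm$rotmat
  # the SVD iteration's criterion-based stop leaves ~1e-6 of angle slack;
  # polish with exact planar rotations (on the Kaiser-normalized matrix,
  # as in the main step) until the stationarity angle vanishes
  p <- nrow(loadings); k <- ncol(loadings)
  h <- sqrt(rowSums(loadings^2))
  An <- (loadings / h) %*% R
  for (sweep in 1:100) {
    max_phi <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        u <- An[, i]^2 - An[, j]^2
        v <- 2 * An[, i] * An[, j]
        num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
        den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
        phi <- atan2(num, den) / 4
        max_phi <- max(max_phi, abs(phi))
        G <- diag(k)
        G[c(i, j), c(i, j)] <- matrix(c(cos(phi), sin(phi),
                                        -sin(phi), cos(phi)), 2)
        An <- An %*% G
        R <- R %*% G
      }
    }
    if (max_phi < 1e-14) break
  }
  list(loadings = An * h, rotmat = R)
}

#' Fit the two-dimensional functional trait space
#'
#' Runs an individual-level principal component analysis on the 15 traits,
#' retains the two leading axes and applies a varimax rotation (Kaiser
#' normalization) to their loading matrix to sharpen interpretability.
#' Right-skewed traits (see [trait_reference()]) are log-transformed first;
#' all traits are then centred and scaled to unit variance, so the PCA is
#' on the correlation structure.
#'
#' Axis orientation follows a fixed convention so refits are deterministic:
#' the rotated axis with the larger absolute loading of vessel density
#' becomes axis 1 (the hydraulic safety--efficiency trade-off) with vessel
#' density loading positively, and axis 2 (investment in tissues) is signed
#' so that wood density loads positively.
#'
#' @param trait_table complete (imputed) trait table with the canonical
#'   trait columns; at least 3 rows.
#' @param log_traits character vector of traits to log-transform; default
#'   per [trait_reference()].
#' @return Object of class `trait_space`: list with `loadings` (15 x 2
#'   rotated correlation loadings), `loadings_raw` (pre-rotation),
#'   `rotmat` (2 x 2 orthogonal rotation), `explained` and `explained_raw`
#'   (percent variance per axis), `scores` (rotated individual scores,
#'   n x 2), `scores_raw`, the transform constants, and the `ids` columns
#'   of the input.
#' @examples
#' com <- generate_community(synthetic_config(n_plots = 2,
#'   individuals_per_plot = 150, seed = 5))
#' ts <- fit_trait_space(impute_traits(com$trait_table, seed = 5)$data)
#' ts
#' @export
fit_trait_space <- function(trait_table, log_traits = NULL) {
  ref <- trait_reference()
  tr <- intersect(ref$trait, names(trait_table))
  if (length(tr) < 2L) stop("need at least two trait columns")
  X <- as.matrix(trait_table[, tr, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 individuals")
  if (any(is.na(X))) {
    stop("trait table has missing values; impute first (impute_traits)")
  }
  if (is.null(log_traits)) log_traits <- ref$trait[ref$log_scale]
  lg <- tr %in% log_traits
  if (any(X[, lg] <= 0)) {
    stop("log-scale trait(s) with non-positive values: ",
         paste(tr[lg][colSums(X[, lg, drop = FALSE] <= 0) > 0],
               collapse = ", "))
  }
  X[, lg] <- log(X[, lg])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("constant trait column(s): ", paste(tr[scl == 0], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (sum(pc$sdev > 1e-12) < 2L) stop("fewer than 2 positive eigenvalues")
  p <- length(tr)
  ev <- pc$sdev^2
  explained_raw <- 100 * ev[1:2] / sum(ev)

  # correlation loadings of the two retained axes
  A <- pc$rotation[, 1:2, drop = FALSE] %*% diag(pc$sdev[1:2])
  S <- pc$x[, 1:2, drop = FALSE]

  vm <- varimax_rotation(A)
  R <- vm$rotmat
  A_rot <- A %*% R
  S_rot <- S %*% R

  # fixed orientation convention
  ord <- c(1L, 2L)
  if ("VD" %in% tr) {
    if (abs(A_rot[match("VD", tr), 2]) > abs(A_rot[match("VD", tr), 1])) {
      ord <- c(2L, 1L)
    }
  }
  A_rot <- A_rot[, ord, drop = FALSE]
  S_rot <- S_rot[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  sgn <- c(1, 1)
  if ("VD" %in% tr && A_rot[match("VD", tr), 1] < 0) sgn[1] <- -1
  if ("WD" %in% tr && A_rot[match("WD", tr), 2] < 0) sgn[2] <- -1
  A_rot <- sweep(A_rot, 2, sgn, "*")
  S_rot <- sweep(S_rot, 2, sgn, "*")
  R <- sweep(R, 2, sgn, "*")

  # correlation PCA: variance share of a rotated axis is its sum of
  # squared correlation loadings over the number of traits
  explained <- 100 * colSums(A_rot^2) / p

  id_cols <- intersect(c("individual_id", "species", "plot", "habit"),
                       names(trait_table))
  dimnames(A_rot) <- list(tr, c("axis1", "axis2"))
  colnames(S_rot) <- c("axis1", "axis2")

  out <- list(traits = tr, log_traits = tr[lg], center = ctr, scale = scl,
              loadings_raw = A, loadings = A_rot, rotmat = R,
              sdev = pc$sdev, rotation_full = pc$rotation,
              explained_raw = explained_raw, explained = explained,
              scores_raw = S, scores = S_rot,
              ids = trait_table[, id_cols, drop = FALSE])
  class(out) <- "trait_space"
  out
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Two-dimensional functional trait space (PCA + varimax)\n")
  cat(sprintf("  individuals: %d, traits: %d\n", nrow(x$scores),
              length(x$traits)))
  cat(sprintf("  retained variance: %.2f%% (axis 1 %.2f%%, axis 2 %.2f%%)\n",
              sum(x$explained), x$explained[1], x$explained[2]))
  invisible(x)
}

#' @export
summary.trait_space <- function(object, ...) {
  print(object)
  cat("\nRotated loadings:\n")
  print(round(object$loadings, 3))
  invisible(object)
}

#' Project new individuals into a fitted trait space
#'
#' @param object a [fit_trait_space()] model.
#' @param newdata trait table with the model's trait columns, complete.
#' @param ... unused.
#' @return n x 2 matrix of rotated scores.
#' @export
predict.trait_space <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$traits, drop = FALSE])
  lg <- object$traits %in% object$log_traits
  X[, lg] <- log(X[, lg])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  S <- Z %*% object$rotation_full[, 1:2, drop = FALSE]
  out <- S %*% object$rotmat
  colnames(out) <- c("axis1", "axis2")
  out
}

#' @export
plot.trait_space <- function(x, ...) {
  graphics::plot(x$scores, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.5, 0.5),
                 xlab = sprintf("Axis 1 (%.1f%%)", x$explained[1]),
                 ylab = sprintf("Axis 2 (%.1f%%)", x$explained[2]), ...)
  sc <- 0.9 * max(abs(x$scores))
  graphics::arrows(0, 0, x$loadings[, 1] * sc, x$loadings[, 2] * sc,
                   length = 0.05, col = "firebrick")
  graphics::text(x$loadings * sc * 1.08, labels = rownames(x$loadings),
                 cex = 0.7, col = "firebrick")
  invisible(x)
}

#' Check that varimax preserved the coordinate system
#'
#' Computes, per rotated axis, the Spearman rank correlation between
#' pre-rotation and post-rotation individual scores. Axes are matched by
#' maximal absolute correlation and sign-aligned; a rotation that merely
#' relabels or reflects the axes therefore reports rho = 1. Axes with
#' rho below `threshold` are flagged.
#'
#' @param model a [fit_trait_space()] model.
#' @param threshold minimal acceptable rank correlation (default 0.9).
#' @return Object of class `rotation_fidelity`: list with `rho` (per
#'   matched axis), `matching`, `flagged`, `threshold`.
#' @export
check_rotation_fidelity <- function(model, threshold = 0.9) {
  stopifnot(inherits(model, "trait_space"))
  C <- stats::cor(model$scores, model$scores_raw, method = "spearman")
  # greedy match by |correlation|
  rho <- numeric(2)
  matching <- integer(2)
  used <- logical(2)
  for (k in order(-apply(abs(C), 1, max))) {
    j <- which.max(ifelse(used, -Inf, abs(C[k, ])))
    matching[k] <- j
    used[j] <- TRUE
    rho[k] <- abs(C[k, j])
  }
  out <- list(rho = stats::setNames(rho, c("axis1", "axis2")),
              matching = matching, flagged = any(rho < threshold),
              threshold = threshold)
  class(out) <- "rotation_fidelity"
  out
}

#' @export
print.rotation_fidelity <- function(x, ...) {
  cat("Rotation fidelity (rank correlation of pre- vs post-rotation scores)\n")
  cat(sprintf("  axis 1: rho = %.3f (matched to raw axis %d)\n",
              x$rho[1], x$matching[1]))
  cat(sprintf("  axis 2: rho = %.3f (matched to raw axis %d)\n",
              x$rho[2], x$matching[2]))
  cat(if (x$flagged) {
    sprintf("  WARNING: rotation moved the coordinate system (rho < %.2f)\n",
            x$threshold)
  } else {
    "  coordinate system preserved\n"
  })
  invisible(x)
}
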