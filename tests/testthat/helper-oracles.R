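# Independent oracles used across the suite. These are deliberately
# written from first principles (textbook algorithms, brute-force
# integration) and share no code with the package internals they check.

# Textbook varimax: Kaiser-normalized pairwise planar rotations.
oracle_varimax <- function(A, max_sweeps = 5000, eps = 1e-14) {
  p <- nrow(A); k <- ncol(A)
  h <- sqrt(rowSums(A^2))
  An <- A / h
  R <- diag(k)
  for (sweep in seq_len(max_sweeps)) {
    max_phi <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        x <- An[, i]; y <- An[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
        den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) > max_phi) max_phi <- abs(phi)
        G <- diag(k)
        G[i, i] <- cos(phi); G[j, j] <- cos(phi)
        G[i, j] <- -sin(phi); G[j, i] <- sin(phi)
        An <- An %*% G
        R <- R %*% G
      }
    }
    if (max_phi < eps) break
  }
  list(loadings = An * h, rotmat = R)
}

# Align columns of B to A up to order and sign (for rotation comparisons).
align_columns <- function(B, A) {
  k <- ncol(A)
  C <- abs(crossprod(A, B))
  ord <- integer(k); used <- logical(k)
  for (i in seq_len(k)) {
    j <- which.max(ifelse(used, -Inf, C[i, ]))
    ord[i] <- j; used[j] <- TRUE
  }
  B <- B[, ord, drop = FALSE]
  for (i in seq_len(k)) if (sum(A[, i] * B[, i]) < 0) B[, i] <- -B[, i]
  B
}

# Brute-force overlap of two isotropic bivariate Gaussians (unit SD sigma)
# separated by distance d, by fine-grid numeric integration.
oracle_gaussian_overlap <- function(d, sigma = 1, half_width = 8,
                                    n = 1201) {
  xs <- seq(-half_width, half_width + d, length.out = n)
  ys <- seq(-half_width, half_width, length.out = n)
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  fa <- outer(stats::dnorm(xs, 0, sigma), stats::dnorm(ys, 0, sigma))
  fb <- outer(stats::dnorm(xs, d, sigma), stats::dnorm(ys, 0, sigma))
  sum(pmin(fa, fb)) * dx * dy
}

# Unit-tracked recomputation of theoretical xylem conductivity:
# all conversions written out longhand.
oracle_conductivity <- function(dh_um, vd_per_mm2) {
  rho_kg_m3 <- 998.2
  eta_MPa_s <- 1.002e-9
  dh_m <- dh_um / 1e6
  vd_m2 <- vd_per_mm2 * 1e3 * 1e3
  (pi * rho_kg_m3 / (128 * eta_MPa_s)) * dh_m^4 * vd_m2
}
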