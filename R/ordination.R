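#' Principal coordinate analysis (PCoA)
#'
#' Metric ordination of a distance matrix: Gower double-centering of
#' -0.5 * D^2, symmetric eigendecomposition, coordinates scaled by the square
#' root of each positive eigenvalue. Axes from negative eigenvalues (possible
#' for semimetric indices such as Bray-Curtis) are dropped and counted; no
#' Lingoes/Cailliez correction is applied. Axis signs follow a deterministic
#' convention: the largest-magnitude loading of each axis is made positive.
#'
#' @param D a `dist_matrix`.
#' @param n_axes number of axes to return (default 3). Truncated with a
#'   warning when fewer positive eigenvalues exist.
#' @return An `ordination_result`: list(labels, coordinates, eigenvalues,
#'   proportion_explained, n_negative_eigenvalues).
#' @export
pcoa <- function(D, n_axes = 3) {
  if (n_axes < 2) validation_error("n_axes must be >= 2")
  d <- unclass(D)
  n <- nrow(d)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  b <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  pos <- e$values > tol
  n_neg <- sum(e$values < -tol)
  k <- min(n_axes, sum(pos))
  if (k < n_axes) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axes", sum(pos), k))
  }
  if (k == 0) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(d), NULL))
    prop <- numeric(0)
  } else {
    lam <- e$values[seq_len(k)]
    coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
    for (j in seq_len(k)) {
      i_max <- which.max(abs(coords[, j]))
      if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
    }
    dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(k)))
    prop <- lam / sum(e$values[pos])
  }
  structure(list(labels = rownames(d), coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = prop,
                 n_negative_eigenvalues = n_neg),
            class = "ordination_result")
}

# Center, zero-pad to n_axes columns, and scale to unit Frobenius norm.
procrustes_prepare <- function(ord, n_axes) {
  x <- ord$coordinates
  if (ncol(x) < n_axes) {
    warning(sprintf("ordination has %d axes; zero-padding to %d", ncol(x), n_axes))
    x <- cbind(x, matrix(0, nrow(x), n_axes - ncol(x)))
  }
  x <- x[, seq_len(n_axes), drop = FALSE]
  x <- scale(x, center = TRUE, scale = FALSE)
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) validation_error("degenerate (all-identical) configuration")
  list(x = x / nrm, center = attr(x, "scaled:center"), norm = nrm)
}

#' Least-squares Procrustes superimposition of two ordinations
#'
#' Both configurations are centered and scaled to unit root sum of squares
#' (symmetric scaling); the optimal orthogonal transform (reflections
#' allowed) comes from the singular decomposition of the cross-covariance.
#' The goodness of fit is M^2 = 1 - (sum of singular values)^2, the minimized
#' residual sum of squares, symmetric in the two configurations.
#'
#' @param X,Y `ordination_result` objects over the same samples, same order.
#' @param n_axes number of leading axes compared (default 3).
#' @return A `procrustes_result`: list(m_squared, rotation, scale,
#'   translation, n_axes, labels).
#' @export
procrustes_fit <- function(X, Y, n_axes = 3) {
  if (!identical(X$labels, Y$labels)) {
    join_error("ordinations must share sample labels and order")
  }
  px <- procrustes_prepare(X, n_axes)
  py <- procrustes_prepare(Y, n_axes)
  sv <- svd(crossprod(py$x, px$x))
  rotation <- sv$u %*% t(sv$v)
  trace_sum <- sum(sv$d)
  m2 <- max(0, 1 - trace_sum^2)
  structure(list(m_squared = m2,
                 rotation = rotation,
                 scale = trace_sum,
                 translation = px$center,
                 n_axes = n_axes,
                 labels = X$labels,
                 X_scaled = px$x, Y_scaled = py$x),
            class = "procrustes_result")
}

#' Procrustes fit with Monte-Carlo significance
#'
#' Null distribution of M^2 by random row relabeling of the second
#' configuration; p = (1 + #\{M^2_perm <= M^2_obs\}) / (1 + n_perm).
#'
#' @inheritParams procrustes_fit
#' @param n_perm number of Monte-Carlo permutations (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @return A `procrustes_result` with `p`, `n_permutations` and `seed` added.
#' @export
procrustes_monte_carlo <- function(X, Y, n_axes = 3, n_perm = 1000, seed = 1) {
  fit <- procrustes_fit(X, Y, n_axes)
  xs <- fit$X_scaled
  ys <- fit$Y_scaled
  n <- nrow(xs)
  m2_for <- function(perm) {
    yp <- scale(ys[perm, , drop = FALSE], center = TRUE, scale = FALSE)
    yp <- yp / sqrt(sum(yp^2))
    max(0, 1 - sum(svd(crossprod(yp, xs))$d)^2)
  }
  m2_null <- withr::with_seed(seed, replicate(n_perm, m2_for(sample.int(n))))
  fit$p <- (1 + sum(m2_null <= fit$m_squared)) / (1 + n_perm)
  fit$n_permutations <- n_perm
  fit$seed <- seed
  fit
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: M^2 = %.4f over %d axes", x$m_squared, x$n_axes))
  if (!is.null(x$p)) cat(sprintf(", p = %.5g (%d permutations)", x$p, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Write an ordination to a labeled TSV
#' @param ord an `ordination_result`.
#' @param path output file.
#' @export
write_ordination <- function(ord, path) {
  df <- data.frame(sample_id = ord$labels,
                   as.data.frame(ord$coordinates, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
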