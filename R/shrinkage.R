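# Shrinkage covariance estimation and the orthogonal transform behind the
# linear combination test. Internal orientation is samples x genes; external
# expression files are genes x samples (microarray convention) and are
# transposed exactly once, at ingest.

#' Center the columns of an expression matrix
#'
#' Converts an expression matrix to the internal samples x genes orientation
#' and removes each gene's mean across samples. All downstream covariance and
#' test-statistic computations operate on the centered matrix.
#'
#' @param x Numeric matrix. By default genes x samples (rows are genes), the
#'   usual orientation of expression files; set `orientation` to
#'   `"samples_by_genes"` if rows are already samples.
#' @param orientation Orientation of `x`.
#' @return An object of class `centered_matrix`: a list with `values`
#'   (samples x genes, each column mean zero) and `column_means` (the removed
#'   per-gene means).
#' @examples
#' x <- matrix(rnorm(20), nrow = 4)  # 4 genes x 5 samples
#' xc <- center_columns(x)
#' colSums(xc$values)  # ~0
#' @export
center_columns <- function(x, orientation = c("genes_by_samples", "samples_by_genes")) {
  orientation <- match.arg(orientation)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (orientation == "genes_by_samples") x <- t(x)
  if (nrow(x) < 2L) stop("insufficient samples: need at least 2, got ", nrow(x))
  mu <- colMeans(x)
  structure(
    list(values = sweep(x, 2L, mu, "-"), column_means = mu),
    class = "centered_matrix"
  )
}

#' @export
print.centered_matrix <- function(x, ...) {
  cat(sprintf("<centered_matrix: %d samples x %d genes>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Sample covariance matrix of a centered expression matrix
#'
#' Unbiased (n-1 denominator) covariance between genes,
#' \eqn{\hat\omega_{hh'} = \sum_l (x_{hl}-\bar x_h)(x_{h'l}-\bar x_{h'})/(n-1)}.
#'
#' @param xc A `centered_matrix` from [center_columns()].
#' @return A p x p symmetric numeric matrix.
#' @export
sample_covariance <- function(xc) {
  stopifnot(inherits(xc, "centered_matrix"))
  n <- nrow(xc$values)
  crossprod(xc$values) / (n - 1)
}

#' Optimal shrinkage intensity for the correlation matrix
#'
#' Estimates the Schafer-Strimmer shrinkage intensity
#' \eqn{\hat\lambda^* = \sum_{h \ne h'} \widehat{Var}(\hat\rho_{hh'}) /
#' \sum_{h \ne h'} \hat\rho_{hh'}^2}, with the sampling variance of each
#' sample correlation estimated empirically from the per-sample products of
#' standardized residuals:
#' \eqn{\widehat{Var}(\hat\rho_{hh'}) = \frac{n}{(n-1)^3}
#' \sum_l (w_{hh'l} - \bar w_{hh'})^2}, where
#' \eqn{w_{hh'l} = z_{hl} z_{h'l}} and \eqn{z_{hl}} are the standardized
#' (mean 0, unit sample-sd) expression values.
#'
#' @param xc A `centered_matrix`; needs at least 3 samples.
#' @return The intensity clamped to \[0, 1\]. With a single gene, or when all
#'   off-diagonal sample correlations are exactly zero, the intensity is 1 by
#'   convention ("shrink fully"; the covariance matrix is already diagonal so
#'   the shrunk matrix is unaffected).
#' @export
shrinkage_intensity <- function(xc) {
  stopifnot(inherits(xc, "centered_matrix"))
  x <- xc$values
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3L) stop("insufficient samples: shrinkage intensity needs at least 3")
  if (p == 1L) return(1)
  sds <- sqrt(colSums(x^2) / (n - 1))
  if (any(sds == 0)) {
    stop("degenerate gene: zero variance in column(s) ",
         paste(which(sds == 0), collapse = ", "))
  }
  z <- sweep(x, 2L, sds, "/")
  rho <- crossprod(z) / (n - 1)
  diag(rho) <- 0
  denom <- sum(rho^2)
  if (denom == 0) return(1)
  # sum over pairs of sum_l w_l^2 via crossprod of squared z; the cross term
  # (sum_l w_l)^2 / n equals (n-1)^2 rho^2 / n
  s2 <- crossprod(z^2)
  diag(s2) <- 0
  var_sum <- n / (n - 1)^3 * (sum(s2) - (n - 1)^2 / n * denom)
  min(1, max(0, var_sum / denom))
}

#' Shrinkage covariance estimate with stored eigendecomposition
#'
#' Forms the shrunk covariance matrix
#' \eqn{\hat\omega^*_{hh'} = \hat\rho_{hh'} \, \min(1, \max(0, 1-\hat\lambda^*))
#' \sqrt{\hat\omega_{hh}\hat\omega_{h'h'}}} off the diagonal, keeping the
#' sample variances on the diagonal, then eigendecomposes it once,
#' \eqn{\hat\Omega^* = U D U^\top}. The stored `transform` \eqn{U D^{-1/2}}
#' (restricted to components whose eigenvalue exceeds a relative cutoff)
#' whitens the shrunk covariance and is what makes the permutation test cheap:
#' it is computed once per dataset, never per permutation.
#'
#' @param xc A `centered_matrix`; needs at least 3 samples and no
#'   zero-variance gene (callers should filter such genes first).
#' @param lambda Optional shrinkage intensity override in \[0, 1\]; by default
#'   estimated with [shrinkage_intensity()]. Mainly useful for checking the
#'   no-shrinkage and full-shrinkage limits.
#' @param eigen_rtol Components with eigenvalue below `eigen_rtol` times the
#'   largest eigenvalue are dropped from `transform` so that \eqn{D^{-1/2}}
#'   cannot amplify numerical noise.
#' @return An object of class `shrinkage_fit`: `lambda_star`, `omega_star`,
#'   `eigvecs` (U, all p columns), `eigvals` (descending), `transform`
#'   (p x k, k retained components), and `n_samples`.
#' @examples
#' xc <- center_columns(matrix(rnorm(60), nrow = 6))  # 6 genes x 10 samples
#' fit <- shrink_covariance(xc)
#' fit$lambda_star
#' # whitening identity:
#' max(abs(t(fit$transform) %*% fit$omega_star %*% fit$transform - diag(ncol(fit$transform))))
#' @export
shrink_covariance <- function(xc, lambda = NULL, eigen_rtol = 1e-10) {
  stopifnot(inherits(xc, "centered_matrix"))
  x <- xc$values
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3L) stop("insufficient samples: shrinkage fit needs at least 3")
  v <- colSums(x^2) / (n - 1)
  if (any(v == 0)) {
    stop("degenerate gene: zero variance in column(s) ",
         paste(which(v == 0), collapse = ", "))
  }
  if (is.null(lambda)) lambda <- shrinkage_intensity(xc)
  shrink <- min(1, max(0, 1 - lambda))
  omega <- crossprod(x) / (n - 1)
  sd_outer <- sqrt(tcrossprod(v))
  rho <- omega / sd_outer
  omega_star <- shrink * rho * sd_outer
  diag(omega_star) <- v
  eg <- eigen(omega_star, symmetric = TRUE)
  d <- eg$values
  keep <- d > eigen_rtol * d[1L]
  transform <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(d[keep]), nrow = sum(keep))
  structure(
    list(lambda_star = lambda, omega_star = omega_star,
         eigvecs = eg$vectors, eigvals = d,
         transform = transform, n_samples = n),
    class = "shrinkage_fit"
  )
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("<shrinkage_fit: p = %d, lambda* = %.4f, %d/%d components retained>\n",
              length(x$eigvals), x$lambda_star, ncol(x$transform), length(x$eigvals)))
  invisible(x)
}

#' Orthogonal transform of the centered expression matrix
#'
#' Computes \eqn{V = X_c U D^{-1/2}} over the retained components. The columns
#' of V are uncorrelated under the shrunk covariance:
#' \eqn{(U D^{-1/2})^\top \hat\Omega^* (U D^{-1/2}) = I_k}. The linear
#' combination test statistic is a plain sum of squared covariances in this
#' basis.
#'
#' @param xc The `centered_matrix` the fit was computed from.
#' @param fit A `shrinkage_fit` from [shrink_covariance()].
#' @return An n x k numeric matrix.
#' @export
orthogonal_transform <- function(xc, fit) {
  stopifnot(inherits(xc, "centered_matrix"), inherits(fit, "shrinkage_fit"))
  if (ncol(xc$values) != nrow(fit$transform)) {
    stop("fit was computed for ", nrow(fit$transform), " genes but matrix has ",
         ncol(xc$values))
  }
  xc$values %*% fit$transform
}
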