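# The four self-contained gene set statistics for a continuous phenotype, and
# the permutation machinery that turns any of them into a p-value. The
# expensive gene-side quantities (shrinkage eigendecomposition, transformed
# matrix V) depend only on the expression data, so they are computed once and
# reused across all phenotype permutations.

GSA_METHODS <- c("LCT", "LCT2", "SAMGS", "GLOBAL")

#' Phenotype vector with stored centering
#'
#' @param values Numeric vector, one phenotype measurement per sample.
#' @return An object of class `phenotype` with `values` and `centered_values`
#'   (mean removed).
#' @export
phenotype <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("insufficient samples: phenotype needs at least 2")
  if (anyNA(values)) stop("phenotype contains missing values")
  structure(list(values = values, centered_values = values - mean(values)),
            class = "phenotype")
}

as_phenotype <- function(y) if (inherits(y, "phenotype")) y else phenotype(y)

#' Linear combination test statistic
#'
#' The LCT statistic is the squared sample correlation of the phenotype with
#' the most-significant linear combination of the set's genes. After the
#' orthogonal transform \eqn{V = X_c U D^{-1/2}} it reduces (up to a constant
#' that cancels in the permutation test) to
#' \eqn{\sum_j \widehat{Cov}(Y, V_j)^2}, algebraically equal to the quadratic
#' form \eqn{\widehat{Cov}(Y,X)^\top \hat\Omega^{*-1} \widehat{Cov}(Y,X)}.
#'
#' @param y A `phenotype` (or numeric vector).
#' @param v The n x k transformed matrix from [orthogonal_transform()].
#' @return Nonnegative scalar.
#' @export
lct_statistic <- function(y, v) {
  y <- as_phenotype(y)
  if (length(y$values) != nrow(v)) {
    stop("phenotype length ", length(y$values), " does not match ", nrow(v), " samples")
  }
  n <- nrow(v)
  sum((crossprod(v, y$centered_values) / (n - 1))^2)
}

#' Modified linear combination test statistic (LCT2)
#'
#' Squared L2 norm of the shrinkage regression function estimate
#' \eqn{\hat f^* = X_c ((n-1)\hat\Omega^*)^{-1} X_c^\top Y_c}: the centered
#' Gram matrix \eqn{X_c^\top X_c = (n-1)\hat\Omega} of the least squares
#' projection is replaced by its shrunk counterpart, which reduces to ordinary
#' least squares fitted values when \eqn{\hat\lambda^* = 0} and stays defined
#' when p > n. The inverse is applied through the stored eigendecomposition.
#'
#' @inheritParams lct_statistic
#' @param xc The `centered_matrix` for the gene set.
#' @param fit The matching `shrinkage_fit`.
#' @return Nonnegative scalar.
#' @export
lct2_statistic <- function(y, xc, fit) {
  y <- as_phenotype(y)
  v <- orthogonal_transform(xc, fit)
  if (length(y$values) != nrow(v)) {
    stop("phenotype length ", length(y$values), " does not match ", nrow(v), " samples")
  }
  n <- nrow(v)
  f <- v %*% crossprod(v, y$centered_values) / (n - 1)
  sum(f^2)
}

#' Continuous-phenotype SAM-GS statistic
#'
#' Sum over the set's genes of the squared Wald statistic from the per-gene
#' simple linear regression \eqn{Y_i = \alpha_0 + \alpha_1 x_{hi} + e_i}:
#' \eqn{\sum_h (\hat\alpha_1^{(h)} / SE(\hat\alpha_1^{(h)}))^2}. Each term
#' equals \eqn{(n-2) r_h^2 / (1 - r_h^2)} with \eqn{r_h} the sample
#' correlation of gene h with the phenotype.
#'
#' @inheritParams lct2_statistic
#' @return Nonnegative scalar.
#' @export
samgs_statistic <- function(y, xc) {
  y <- as_phenotype(y)
  x <- xc$values
  n <- nrow(x)
  if (length(y$values) != n) {
    stop("phenotype length ", length(y$values), " does not match ", n, " samples")
  }
  if (n < 4L) stop("insufficient samples: per-gene regression needs at least 4")
  sy <- sqrt(sum(y$centered_values^2))
  sx <- sqrt(colSums(x^2))
  if (sy == 0) return(0)
  if (any(sx == 0)) {
    stop("degenerate gene: zero variance in column(s) ",
         paste(which(sx == 0), collapse = ", "))
  }
  r2 <- pmin(as.vector(crossprod(x, y$centered_values) / (sx * sy))^2, 1)
  if (any(r2 > 1 - 1e-12)) {
    stop("degenerate regression: gene(s) ",
         paste(which(r2 > 1 - 1e-12), collapse = ", "),
         " perfectly collinear with the phenotype")
  }
  sum((n - 2) * r2 / (1 - r2))
}

#' Global Test score statistic
#'
#' Quadratic-form score statistic of the random-effects formulation in which
#' the per-gene regression coefficients share a zero-mean common distribution:
#' \eqn{Q = (Y-\bar Y)^\top X_c X_c^\top (Y-\bar Y) / p}. Scaling constants
#' are permutation invariant; 1/p keeps values comparable across set sizes.
#'
#' @inheritParams lct2_statistic
#' @return Nonnegative scalar.
#' @export
globaltest_statistic <- function(y, xc) {
  y <- as_phenotype(y)
  x <- xc$values
  if (length(y$values) != nrow(x)) {
    stop("phenotype length ", length(y$values), " does not match ", nrow(x), " samples")
  }
  sum(crossprod(x, y$centered_values)^2) / ncol(x)
}

#' Seeded phenotype permutation index matrix
#'
#' One shared index matrix is used across all statistics (and, in screening,
#' across all gene sets) of a comparison run so that differences between
#' methods are not confounded by permutation noise.
#'
#' @param n Number of samples.
#' @param B Number of permutations.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An n x B integer matrix, each column a permutation of `1:n`.
#' @export
make_permutations <- function(n, B, seed = NULL) {
  if (B < 1L) stop("number of permutations must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

#' Permutation p-value for an arbitrary statistic
#'
#' Permutes the phenotype labels and reports
#' \eqn{p = (1 + \#\{b: T(Y_{\pi_b}) \ge T(Y)\}) / (B + 1)}; the add-one
#' convention guarantees p > 0 and an exact test, and ties count towards the
#' numerator. The statistic callable receives only the (permuted) phenotype;
#' any gene-side quantities should be captured in its closure, computed once.
#'
#' @param stat Function taking a numeric phenotype vector and returning a
#'   scalar statistic (larger = more extreme).
#' @param y A `phenotype` or numeric vector.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @param method Label stored in the result.
#' @return An object of class `gsa_test_result`: `statistic`, `p_value`,
#'   `n_permutations`, `method`, `seed`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), nrow = 10)  # 20 genes x 10 samples
#' xc <- center_columns(x)
#' v <- orthogonal_transform(xc, shrink_covariance(xc))
#' y <- rnorm(10)
#' permutation_pvalue(function(yy) lct_statistic(yy, v), y, B = 99, seed = 7)
#' @export
permutation_pvalue <- function(stat, y, B, seed = NULL, method = "custom") {
  if (B < 1L) stop("number of permutations must be at least 1")
  y <- as_phenotype(y)
  observed <- stat(y$values)
  perms <- make_permutations(length(y$values), B, seed)
  permuted <- vapply(seq_len(B), function(b) stat(y$values[perms[, b]]), numeric(1L))
  structure(
    list(statistic = observed,
         p_value = (1 + sum(permuted >= observed)) / (B + 1),
         n_permutations = B, method = method,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "gsa_test_result"
  )
}

#' @export
print.gsa_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

# Vectorized permutation engine used by the simulation and screening layers.
# All four statistics reduce to column operations on crossprod(<basis>, Yperm)
# where Yperm holds the observed centered phenotype and its B permutations,
# so one or two BLAS calls cover the whole permutation distribution.
#
# xc: centered_matrix for the set; y: phenotype; perms: n x B index matrix.
# Returns data.frame(method, statistic, p_value, n_permutations).
gsa_test_engine <- function(xc, y, methods, perms, fit = NULL) {
  methods <- match.arg(methods, GSA_METHODS, several.ok = TRUE)
  y <- as_phenotype(y)
  x <- xc$values
  n <- nrow(x)
  if (length(y$values) != n) {
    stop("phenotype length ", length(y$values), " does not match ", n, " samples")
  }
  B <- ncol(perms)
  yc <- y$centered_values
  ymat <- cbind(yc, matrix(yc[perms], nrow = n))
  need_fit <- any(methods %in% c("LCT", "LCT2"))
  if (need_fit && is.null(fit)) fit <- shrink_covariance(xc)

  out <- lapply(methods, function(m) {
    stats <- switch(m,
      LCT = {
        v <- x %*% fit$transform
        colSums((crossprod(v, ymat) / (n - 1))^2)
      },
      LCT2 = {
        v <- x %*% fit$transform
        colSums((v %*% (crossprod(v, ymat) / (n - 1)))^2)
      },
      SAMGS = {
        if (n < 4L) stop("insufficient samples: per-gene regression needs at least 4")
        sy <- sqrt(sum(yc^2))
        sx <- sqrt(colSums(x^2))
        if (any(sx == 0)) {
          stop("degenerate gene: zero variance in column(s) ",
               paste(which(sx == 0), collapse = ", "))
        }
        if (sy == 0) {
          rep(0, B + 1L)
        } else {
          r2 <- pmin((crossprod(x, ymat) / (sx * sy))^2, 1 - 1e-15)
          if (any(r2[, 1L] > 1 - 1e-12)) {
            stop("degenerate regression: gene(s) ",
                 paste(which(r2[, 1L] > 1 - 1e-12), collapse = ", "),
                 " perfectly collinear with the phenotype")
          }
          colSums((n - 2) * r2 / (1 - r2))
        }
      },
      GLOBAL = colSums(crossprod(x, ymat)^2) / ncol(x)
    )
    data.frame(method = m, statistic = unname(stats[1L]),
               p_value = (1 + sum(stats[-1L] >= stats[1L])) / (B + 1),
               n_permutations = B, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Test one gene set against a continuous phenotype
#'
#' Computes the requested statistics for a single set and their permutation
#' p-values from one shared, seeded permutation index matrix. The shrinkage
#' eigendecomposition is computed once for the observed expression data; the
#' permutation distribution of every statistic is then obtained with
#' vectorized matrix products.
#'
#' @param x Expression matrix for the set, genes x samples (rows genes), or a
#'   `centered_matrix`.
#' @param y A `phenotype` or numeric vector of length n samples.
#' @param methods Subset of `c("LCT", "LCT2", "SAMGS", "GLOBAL")`.
#' @param B Number of phenotype permutations.
#' @param seed Integer seed for the permutations.
#' @param perms Optional precomputed n x B permutation index matrix
#'   (overrides `B` and `seed`); used by the screening layer to share
#'   permutations across sets.
#' @return A data.frame with one row per method: `method`, `statistic`,
#'   `p_value`, `n_permutations`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), nrow = 30)  # 30 genes x 10 samples
#' gsa_test(x, rnorm(10), B = 99, seed = 2)
#' @export
gsa_test <- function(x, y, methods = GSA_METHODS, B = 1000L, seed = NULL,
                     perms = NULL) {
  xc <- if (inherits(x, "centered_matrix")) x else center_columns(x)
  if (is.null(perms)) perms <- make_permutations(nrow(xc$values), B, seed)
  gsa_test_engine(xc, y, methods, perms)
}
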