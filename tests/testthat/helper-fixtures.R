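# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (scalar loops, dense inverses, textbook formulas) and
# never call the package's own linear-algebra paths.

# fixed 10-sample x 4-gene matrix used by the frozen-value tests
fixture_10x4 <- function() {
  matrix(c(1.371, -0.565, 0.363, 0.633, 0.404, -0.106, 1.512,
           -0.095, 2.018, -0.063, 1.305, 2.287, -1.389, -0.279, -0.133,
           0.636, -0.284, -2.656, -2.44, 1.32, -0.307, -1.781, -0.172, 1.215,
           1.895, -0.43, -0.257, -1.763, 0.46, -0.64, 0.455, 0.705, 1.035,
           -0.609, 0.505, -1.717, -0.784, -0.851, -2.414, 0.036),
         nrow = 10, ncol = 4)
}

fixture_y10 <- function() {
  c(0.214, 0.48, 0.088, 0.444, -0.363, 0.123, -0.864, 0.49, -0.364, -1.294)
}

# random samples x genes matrix
rand_matrix <- function(n, p) matrix(rnorm(n * p), nrow = n, ncol = p)

# two-pass covariance by explicit double loop
oracle_covariance <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xb <- colMeans(x)
  om <- matrix(0, p, p)
  for (h in seq_len(p)) {
    for (k in seq_len(p)) {
      om[h, k] <- sum((x[, h] - xb[h]) * (x[, k] - xb[k])) / (n - 1)
    }
  }
  om
}

# Schafer-Strimmer intensity by scalar loops over gene pairs
oracle_shrinkage_intensity <- function(x) {
  n <- nrow(x); p <- ncol(x)
  if (p == 1) return(1)
  om <- oracle_covariance(x)
  z <- sapply(seq_len(p), function(h) (x[, h] - mean(x[, h])) / sqrt(om[h, h]))
  num <- 0; den <- 0
  for (h in seq_len(p)) {
    for (k in seq_len(p)) {
      if (h != k) {
        w <- z[, h] * z[, k]
        rho <- sum(w) / (n - 1)
        num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
        den <- den + rho^2
      }
    }
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

# shrunk covariance entry by entry
oracle_shrink_covariance <- function(x, lambda) {
  om <- oracle_covariance(x)
  p <- ncol(om)
  shrink <- min(1, max(0, 1 - lambda))
  out <- matrix(0, p, p)
  for (h in seq_len(p)) {
    for (k in seq_len(p)) {
      rho <- om[h, k] / sqrt(om[h, h] * om[k, k])
      out[h, k] <- if (h == k) om[h, h] else rho * shrink * sqrt(om[h, h] * om[k, k])
    }
  }
  out
}

# LCT as the quadratic form in the covariance vector with a dense inverse
oracle_lct_quadform <- function(x, y, omega_star) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  cv <- as.vector(crossprod(xc, y - mean(y))) / (n - 1)
  drop(t(cv) %*% solve(omega_star) %*% cv)
}

# all permutations of 1:n (n small), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

# in-memory synthetic catalog: expression matrix plus a collection with one
# planted signal set and disjoint null sets
synthetic_catalog <- function(n = 30, p_signal = 100, n_null_sets = 199,
                              set_size = 50, rho = 0.6, nu = 2, seed = 1) {
  sc <- simulation_scenario(n = n, p = p_signal, p1 = 20, p2 = 20, rho = rho,
                            nu = nu, n_replicates = 1, n_permutations = 1,
                            seed = seed)
  dat <- simulate_dataset(sc, replicate_seed = seed)
  p_total <- p_signal + n_null_sets * set_size
  x_null <- matrix(rnorm(n * (p_total - p_signal)), nrow = n)
  x <- t(cbind(dat$x, x_null))
  genes <- sprintf("G%05d", seq_len(p_total))
  rownames(x) <- genes
  colnames(x) <- sprintf("S%03d", seq_len(n))
  sets <- list(list(name = "SIGNAL_SET", description = "planted",
                    genes = genes[seq_len(p_signal)]))
  pool <- genes[-seq_len(p_signal)]
  for (k in seq_len(n_null_sets)) {
    sets[[k + 1]] <- list(name = sprintf("NULL_%03d", k), description = "null",
                          genes = pool[(k - 1) * set_size + seq_len(set_size)])
  }
  list(x = x, y = dat$y, coll = gene_set_collection(sets))
}
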