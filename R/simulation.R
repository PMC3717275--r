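# Simulation framework: structured gene-gene correlation, phenotype generated
# from a sparse linear effect, and the type-I-error / power experiments.

#' Block correlation matrix with compound-symmetry and AR(1) blocks
#'
#' The first `p1` genes share a constant pairwise correlation rho (compound
#' symmetry), the next `p2` genes follow an AR(1) structure
#' \eqn{\rho_{ij} = \rho^{|i-j|}}, and the remaining `p - p1 - p2` genes are
#' uncorrelated.
#'
#' @param p Total number of genes.
#' @param p1 Size of the compound-symmetry block.
#' @param p2 Size of the AR(1) block.
#' @param rho Correlation parameter in \[0, 1).
#' @return A p x p correlation matrix (unit diagonal, positive definite for
#'   rho in \[0, 1)).
#' @examples
#' r <- build_correlation_matrix(20, 5, 5, 0.9)
#' r[1, 2]; r[6, 8]; r[13, 14]  # 0.9, 0.81, 0
#' @export
build_correlation_matrix <- function(p, p1, p2, rho) {
  if (p1 < 0 || p2 < 0 || p1 + p2 > p) stop("block sizes must satisfy p1 + p2 <= p")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  r <- diag(p)
  if (p1 > 1) {
    r[seq_len(p1), seq_len(p1)] <- rho
    diag(r)[seq_len(p1)] <- 1
  }
  if (p2 > 1) {
    idx <- p1 + seq_len(p2)
    r[idx, idx] <- rho^abs(outer(seq_len(p2), seq_len(p2), "-"))
  }
  r
}

#' Sparse effect vector for the alternative model
#'
#' Five positions chosen uniformly among the first 20 genes receive draws from
#' \eqn{N(\nu, |\nu|)} and five positions among genes 21-40 receive draws from
#' \eqn{N(-\nu, |\nu|)} (\eqn{|\nu|} read as a variance); all other entries
#' are zero. `nu = 0` gives the null model, a zero vector.
#'
#' @param p Number of genes (at least 40 when `nu > 0`).
#' @param nu Effect scale, >= 0.
#' @param seed Optional integer seed; `NULL` draws from the current RNG state.
#' @return Numeric vector of length p with exactly 10 nonzero entries when
#'   `nu > 0`.
#' @export
draw_mu <- function(p, nu, seed = NULL) {
  if (nu < 0) stop("nu must be nonnegative")
  if (nu == 0) return(numeric(p))
  if (p < 40L) stop("effect vector needs p >= 40 when nu > 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- numeric(p)
  mu[sample.int(20L, 5L)] <- stats::rnorm(5L, mean = nu, sd = sqrt(nu))
  mu[20L + sample.int(20L, 5L)] <- stats::rnorm(5L, mean = -nu, sd = sqrt(nu))
  mu
}

#' Simulation scenario descriptor
#'
#' Bundles and validates the parameters of one simulation condition: sample
#' count, gene count, correlation block sizes, correlation strength, effect
#' scale (0 = null model), replication and permutation counts, nominal
#' levels, and the master seed.
#'
#' @param n Samples per dataset.
#' @param p Genes per set.
#' @param p1,p2 Correlated block sizes (see [build_correlation_matrix()]).
#' @param rho Correlation in \[0, 1).
#' @param nu Effect scale >= 0.
#' @param n_replicates Number of replicate datasets.
#' @param n_permutations Permutations per replicate.
#' @param nominal_levels Nominal type-I-error levels in (0, 1).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n, p, p1, p2, rho, nu = 0,
                                n_replicates = 1000L, n_permutations = 1000L,
                                nominal_levels = c(0.005, 0.01, 0.05),
                                seed = 1L) {
  if (n < 3L) stop("scenario needs at least 3 samples")
  if (p < 1L) stop("scenario needs at least 1 gene")
  if (p1 < 0 || p2 < 0 || p1 + p2 > p) stop("block sizes must satisfy p1 + p2 <= p")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (nu < 0) stop("nu must be nonnegative")
  if (n_replicates < 1L) stop("need at least 1 replicate")
  if (n_permutations < 1L) stop("need at least 1 permutation")
  if (any(nominal_levels <= 0 | nominal_levels >= 1)) {
    stop("nominal levels must lie in (0, 1)")
  }
  structure(
    list(n = as.integer(n), p = as.integer(p), p1 = as.integer(p1),
         p2 = as.integer(p2), rho = rho, nu = nu,
         n_replicates = as.integer(n_replicates),
         n_permutations = as.integer(n_permutations),
         nominal_levels = sort(nominal_levels), seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario: n = %d, p = %d (p1 = %d, p2 = %d), rho = %.2f, nu = %.2f, %d replicates x %d permutations>\n",
    x$n, x$p, x$p1, x$p2, x$rho, x$nu, x$n_replicates, x$n_permutations))
  invisible(x)
}

# deterministic per-replicate seeds: one draw of well-scattered 32-bit
# integers from the scenario seed, so replicates are reproducible,
# order-independent and parallelizable
replicate_seeds <- function(seed, n_replicates) {
  set.seed(seed)
  sample.int(2147483646L, n_replicates)
}

#' Simulate one expression/phenotype dataset
#'
#' Rows of X are i.i.d. multivariate normal with mean 0 and covariance equal
#' to the block correlation matrix (unit gene variances). The phenotype is
#' \eqn{Y \sim N(X\mu, I)} with the sparse effect vector redrawn each
#' replicate; under the null (`nu = 0`) Y is standard normal independent
#' of X.
#'
#' @param sc A `simulation_scenario`.
#' @param replicate_seed Integer seed for this replicate.
#' @param chol_R Optional upper-triangular Cholesky factor of the correlation
#'   matrix, precomputed once per scenario by the experiment drivers.
#' @return A list with `x` (n x p matrix), `y` (length n), and `mu`.
#' @export
simulate_dataset <- function(sc, replicate_seed, chol_R = NULL) {
  stopifnot(inherits(sc, "simulation_scenario"))
  if (is.null(chol_R)) {
    chol_R <- chol(build_correlation_matrix(sc$p, sc$p1, sc$p2, sc$rho))
  }
  set.seed(replicate_seed)
  x <- matrix(stats::rnorm(sc$n * sc$p), nrow = sc$n) %*% chol_R
  mu <- draw_mu(sc$p, sc$nu)
  y <- as.vector(x %*% mu) + stats::rnorm(sc$n)
  list(x = x, y = y, mu = mu)
}

# Shared driver for the size and power experiments: simulates replicates,
# computes permutation p-values for each method, and tallies rejections at
# each nominal level.
run_experiment <- function(sc, methods = GSA_METHODS) {
  methods <- match.arg(methods, GSA_METHODS, several.ok = TRUE)
  chol_R <- chol(build_correlation_matrix(sc$p, sc$p1, sc$p2, sc$rho))
  levels <- sc$nominal_levels
  rejections <- matrix(0L, nrow = length(methods), ncol = length(levels),
                       dimnames = list(methods, NULL))
  rep_seeds <- replicate_seeds(sc$seed, sc$n_replicates)
  for (i in seq_len(sc$n_replicates)) {
    dat <- simulate_dataset(sc, rep_seeds[i], chol_R)
    perms <- make_permutations(sc$n, sc$n_permutations)  # continues replicate RNG
    xc <- center_columns(dat$x, orientation = "samples_by_genes")
    res <- gsa_test_engine(xc, dat$y, methods, perms)
    for (m in seq_along(methods)) {
      p <- res$p_value[res$method == methods[m]]
      rejections[m, ] <- rejections[m, ] + (p <= levels)
    }
  }
  rates <- data.frame(
    method = rep(methods, each = length(levels)),
    level = rep(levels, times = length(methods)),
    rejections = as.vector(t(rejections)),
    rate = as.vector(t(rejections)) / sc$n_replicates
  )
  structure(list(scenario = sc, methods = methods, rates = rates),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  print(x$scenario)
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Empirical type-I-error experiment
#'
#' Runs the null-model experiment: for each replicate, simulate a dataset
#' with `nu = 0`, compute each method's permutation p-value, and report the
#' proportion of replicates rejecting at each nominal level.
#'
#' @param sc A `simulation_scenario` with `nu = 0`.
#' @param methods Methods to evaluate.
#' @return A `simulation_summary` whose `rates` data.frame holds the
#'   per-method, per-level rejection proportions.
#' @export
run_type1_experiment <- function(sc, methods = GSA_METHODS) {
  stopifnot(inherits(sc, "simulation_scenario"))
  if (sc$nu != 0) stop("type-I-error experiment requires the null model (nu = 0)")
  run_experiment(sc, methods)
}

#' Empirical power curve over a grid of effect scales
#'
#' Reruns the simulation experiment at each value of `nu_grid`, reporting the
#' rejection proportion at the given nominal level per method. The `nu = 0`
#' entry of the curve is the type-I error.
#'
#' @param sc A `simulation_scenario` used as the template (its `nu` is
#'   replaced by each grid value).
#' @param nu_grid Ascending vector of effect scales.
#' @param methods Methods to evaluate.
#' @param level Nominal level for the power calculation.
#' @return A data.frame with columns `nu`, `method`, `power`.
#' @export
run_power_curve <- function(sc, nu_grid = seq(0, 5, by = 0.25),
                            methods = GSA_METHODS, level = 0.05) {
  stopifnot(inherits(sc, "simulation_scenario"))
  if (is.unsorted(nu_grid)) stop("nu_grid must be sorted ascending")
  out <- lapply(nu_grid, function(nu) {
    sci <- sc
    sci$nu <- nu
    sci$nominal_levels <- level
    summ <- run_experiment(sci, methods)
    data.frame(nu = nu, method = summ$rates$method, power = summ$rates$rate)
  })
  do.call(rbind, out)
}
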