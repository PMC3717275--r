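# Multi-gene-set screening: gene standardization, set-size filtering, batched
# permutation testing with one shared permutation matrix, Storey q-values.

#' Standardize genes across samples
#'
#' Centers and scales each gene (row) to mean 0, standard deviation 1 (n-1
#' denominator) across samples, the usual preprocessing before self-contained
#' set testing. Zero-variance genes are removed first with a warning.
#'
#' @param x Numeric genes x samples matrix with gene identifiers as rownames.
#' @return The standardized matrix, possibly with fewer rows.
#' @export
standardize_genes <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("insufficient samples: need at least 2")
  sds <- apply(x, 1L, stats::sd)
  zero <- sds == 0
  if (all(zero)) stop("no usable genes: every gene has zero variance")
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) removed: ",
            paste(utils::head(rownames(x)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ..." else "")
    x <- x[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  (x - rowMeans(x)) / sds
}

#' Restrict a gene set collection to testable sets
#'
#' Intersects every set with the genes present in the expression matrix and
#' keeps sets whose analyzed (intersected) size lies in
#' \[`min_size`, `max_size`\], inclusive. The size filter is applied after
#' intersection because testing only ever sees genes present in the matrix.
#'
#' @param coll A `gene_set_collection` (see [read_gmt()] /
#'   [gene_set_collection()]).
#' @param gene_ids Character vector of gene identifiers in the matrix.
#' @param min_size,max_size Inclusive analyzed-size bounds (defaults 15
#'   and 500).
#' @return A filtered `gene_set_collection` whose sets carry an
#'   `annotated_size` attribute with the pre-intersection size.
#' @export
filter_sets <- function(coll, gene_ids, min_size = 15L, max_size = 500L) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (min_size > max_size) stop("min_size must not exceed max_size")
  kept <- list()
  for (s in coll) {
    present <- s$genes[s$genes %in% gene_ids]
    if (length(present) >= min_size && length(present) <= max_size) {
      kept[[length(kept) + 1L]] <- list(name = s$name,
                                        description = s$description,
                                        genes = present,
                                        annotated_size = length(s$genes))
    }
  }
  structure(kept, class = "gene_set_collection")
}

#' Screen a gene set catalog against a continuous phenotype
#'
#' The full screening pipeline: standardize genes, filter sets by analyzed
#' size, test every retained set with every requested method using one shared
#' seeded permutation index matrix (so p-values are comparable across sets
#' and methods), and append Storey q-values per method.
#'
#' @param x Genes x samples expression matrix with gene identifiers as
#'   rownames.
#' @param y A `phenotype` or numeric vector, one value per sample.
#' @param coll A `gene_set_collection`.
#' @param methods Subset of `c("LCT", "LCT2", "SAMGS", "GLOBAL")`.
#' @param B Number of phenotype permutations.
#' @param seed Integer seed for the shared permutation matrix.
#' @param min_size,max_size Analyzed-size bounds passed to [filter_sets()].
#' @param standardize Standardize genes first (default TRUE).
#' @return A data.frame with one row per retained set: `set`,
#'   `annotated_size`, `analyzed_size`, then `statistic_<m>`, `p_<m>`,
#'   `q_<m>` for each method m.
#' @export
screen <- function(x, y, coll, methods = GSA_METHODS, B = 1000L, seed = NULL,
                   min_size = 15L, max_size = 500L, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("expression matrix must carry gene identifiers as rownames")
  y <- as_phenotype(y)
  if (length(y$values) != ncol(x)) {
    stop("phenotype length ", length(y$values), " does not match ", ncol(x), " samples")
  }
  methods <- match.arg(methods, GSA_METHODS, several.ok = TRUE)
  if (standardize) x <- standardize_genes(x)
  kept <- filter_sets(coll, rownames(x), min_size, max_size)
  if (length(kept) == 0L) {
    warning("no gene sets retained after size filtering")
    return(data.frame(set = character(), annotated_size = integer(),
                      analyzed_size = integer()))
  }
  perms <- make_permutations(ncol(x), B, seed)
  rows <- lapply(kept, function(s) {
    idx <- match(s$genes, rownames(x))
    xc <- center_columns(t(x[idx, , drop = FALSE]),
                         orientation = "samples_by_genes")
    res <- gsa_test_engine(xc, y, methods, perms)
    row <- data.frame(set = s$name, annotated_size = s$annotated_size,
                      analyzed_size = length(s$genes))
    for (m in methods) {
      row[[paste0("statistic_", m)]] <- res$statistic[res$method == m]
      row[[paste0("p_", m)]] <- res$p_value[res$method == m]
    }
    row
  })
  out <- do.call(rbind, rows)
  for (m in methods) out[[paste0("q_", m)]] <- storey_qvalues(out[[paste0("p_", m)]])
  ord <- c("set", "annotated_size", "analyzed_size",
           as.vector(t(outer(c("statistic_", "p_", "q_"), methods, paste0))))
  out[, ord]
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the simple point estimate of the null
#' proportion, \eqn{\hat\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m)}
#' at \eqn{\lambda = 0.5}, and the step-up running minimum
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 \, m \, p_{(j)} / j}. With
#' \eqn{\hat\pi_0 = 1} this reduces to Benjamini-Hochberg adjusted p-values.
#'
#' @param pvals Numeric vector of p-values in (0, 1\].
#' @param lambda Tuning point for the null-proportion estimate.
#' @return q-values in the input order.
#' @export
storey_qvalues <- function(pvals, lambda = 0.5) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(pvals)
  pi0 <- min(1, sum(pvals > lambda) / ((1 - lambda) * m))
  o <- order(pvals)
  q_sorted <- rev(cummin(rev(pi0 * m * pvals[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
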