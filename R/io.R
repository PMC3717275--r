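# Tab-delimited expression and phenotype files, and fixture generation for
# end-to-end runs. Parsing is strict: the statistics assume complete numeric
# matrices, so missing or malformed cells fail loudly rather than being
# coerced.

#' Read a genes x samples expression matrix from TSV
#'
#' Expected layout: a header row whose first field names the gene-identifier
#' column and whose remaining fields are sample identifiers, then one row per
#' gene. Every cell must parse as a number; ragged rows, non-numeric cells
#' and duplicate gene identifiers are errors.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, rownames = gene identifiers, colnames = sample
#'   identifiers.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty expression matrix: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (length(samples) == 0L) stop("expression file has no sample columns")
  if (anyDuplicated(samples)) stop("duplicate sample identifier(s) in header")
  p <- length(lines) - 1L
  genes <- character(p)
  mat <- matrix(NA_real_, nrow = p, ncol = length(samples))
  for (i in seq_len(p)) {
    f <- fields[[i + 1L]]
    if (length(f) != length(samples) + 1L) {
      stop("ragged row at line ", i + 1L, ": expected ", length(samples) + 1L,
           " fields, got ", length(f))
    }
    genes[i] <- f[1L]
    vals <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop("non-numeric value '", f[j + 1L], "' for gene ", f[1L],
           ", sample ", samples[j])
    }
    mat[i, ] <- vals
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  dimnames(mat) <- list(genes, samples)
  mat
}

#' Write a genes x samples expression matrix to TSV
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param id_column Header of the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "gene") {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene rownames and sample colnames")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a phenotype file
#'
#' Two tab-separated columns, sample identifier and numeric value, with a
#' header row.
#'
#' @param path Path to the TSV file.
#' @return A named numeric vector (names = sample identifiers).
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = c("character", "character"))
  if (ncol(df) != 2L) stop("phenotype file must have exactly 2 columns")
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(vals)) {
    stop("non-numeric phenotype value for sample ", df[[1L]][which(is.na(vals))[1L]])
  }
  if (anyDuplicated(df[[1L]])) stop("duplicate sample identifier(s) in phenotype file")
  stats::setNames(vals, df[[1L]])
}

#' Write a phenotype file
#'
#' @param y Named numeric vector (names = sample identifiers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(y, path) {
  if (is.null(names(y))) stop("phenotype vector must be named by sample")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample\tvalue", con)
  writeLines(paste(names(y), format(y, digits = 15, trim = TRUE,
                                    scientific = FALSE), sep = "\t"), con)
  invisible(path)
}

#' Generate a consistent expression/phenotype/catalog fixture on disk
#'
#' Writes a trio of files with the statistical structure of the simulation
#' model: an expression matrix of `p_total` genes over `n` samples whose
#' first `p_signal` genes follow the block correlation structure and carry
#' the sparse `nu`-scaled effect on the phenotype, a phenotype file, and a
#' GMT catalog whose first set ("SIGNAL_SET") holds the signal genes and
#' whose remaining `n_null_sets` sets are disjoint draws from the null
#' genes. Deterministic per seed.
#'
#' @param dir Output directory (created if absent).
#' @param n Samples.
#' @param p_total Total genes in the matrix.
#' @param p_signal Genes in the signal set (>= 40 when `nu > 0`).
#' @param n_null_sets Number of null gene sets.
#' @param set_size Size of each null set.
#' @param rho Correlation in the signal set's structured blocks.
#' @param p1,p2 Block sizes within the signal set.
#' @param nu Effect scale; 0 gives an entirely null fixture.
#' @param seed Integer seed.
#' @return A list of paths: `expression`, `phenotype`, `gmt`.
#' @export
make_fixture <- function(dir, n = 30L, p_total = 2000L, p_signal = 100L,
                         n_null_sets = 19L, set_size = 50L, rho = 0.6,
                         p1 = 20L, p2 = 20L, nu = 0, seed = 1L) {
  if (p_signal + n_null_sets * set_size > p_total) {
    stop("p_total too small for the requested catalog")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- simulation_scenario(n = n, p = p_signal, p1 = p1, p2 = p2, rho = rho,
                            nu = nu, n_replicates = 1L, n_permutations = 1L,
                            seed = seed)
  dat <- simulate_dataset(sc, replicate_seed = seed)
  # null genes: independent standard normal, drawn from the same RNG stream
  x_null <- matrix(stats::rnorm(n * (p_total - p_signal)), nrow = n)
  x <- t(cbind(dat$x, x_null))
  genes <- sprintf("G%05d", seq_len(p_total))
  samples <- sprintf("S%03d", seq_len(n))
  dimnames(x) <- list(genes, samples)

  sets <- list(list(name = "SIGNAL_SET", description = "planted signal",
                    genes = genes[seq_len(p_signal)]))
  pool <- genes[-seq_len(p_signal)]
  for (k in seq_len(n_null_sets)) {
    idx <- (k - 1L) * set_size + seq_len(set_size)
    sets[[k + 1L]] <- list(name = sprintf("NULL_SET_%03d", k),
                           description = "null", genes = pool[idx])
  }
  coll <- gene_set_collection(sets)

  paths <- list(expression = file.path(dir, "expression.tsv"),
                phenotype = file.path(dir, "phenotype.tsv"),
                gmt = file.path(dir, "sets.gmt"))
  write_expression(x, paths$expression)
  write_phenotype(stats::setNames(dat$y, samples), paths$phenotype)
  write_gmt(coll, paths$gmt)
  paths
}
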