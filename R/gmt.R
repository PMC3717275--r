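# GMT gene set catalogs: one set per line, tab-separated as
# name <TAB> description <TAB> gene1 <TAB> gene2 ...

#' Construct a gene set collection
#'
#' @param sets A list of lists, each with `name` (string), `description`
#'   (string), and `genes` (character vector). Names must be unique, sets
#'   nonempty; duplicate genes within a set are removed with a warning.
#' @return An object of class `gene_set_collection`, an ordered list of sets.
#' @export
gene_set_collection <- function(sets) {
  sets <- lapply(sets, function(s) {
    if (is.null(s$name) || !nzchar(s$name)) stop("gene set without a name")
    if (length(s$genes) == 0L) stop("gene set '", s$name, "' is empty")
    genes <- as.character(s$genes)
    if (anyDuplicated(genes)) {
      warning("duplicate gene identifier(s) in set '", s$name, "' removed")
      genes <- unique(genes)
    }
    list(name = as.character(s$name),
         description = as.character(s$description %||% ""),
         genes = genes)
  })
  nm <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  structure(sets, class = "gene_set_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1L))
  cat(sprintf("<gene_set_collection: %d sets", length(x)))
  if (length(x)) cat(sprintf(", sizes %d-%d", min(sizes), max(sizes)))
  cat(">\n")
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  structure(unclass(x)[i], class = "gene_set_collection")
}

#' @export
names.gene_set_collection <- function(x) {
  vapply(unclass(x), `[[`, character(1L), "name")
}

#' Read a GMT gene set catalog
#'
#' Strict parser: every nonblank line must have at least three tab-separated
#' fields (name, description, one or more genes). Duplicate genes within a
#' set are removed with a warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`, sets in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  sets <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("malformed GMT line ", lineno[i], ": expected name, description and ",
           "at least one gene, got ", length(f), " field(s)")
    }
    sets[[i]] <- list(name = f[1L], description = f[2L], genes = f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Write a GMT gene set catalog
#'
#' @param coll A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(coll, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
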