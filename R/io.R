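#' Read a haplotype DAG from a tab-separated edge list
#'
#' The file must have a header `child  parent  n_mutations` (the mutation
#' column is optional). An empty `parent` field marks a starting haplotype;
#' a child with several parents occupies several rows.
#'
#' @param path path to a UTF-8 TSV file
#' @return a `haplotype_dag`
#' @export
read_dag <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("", "NA"))
  if ("n_mutations" %in% names(tab))
    tab$n_mutations <- as.numeric(tab$n_mutations)
  haplotype_dag(tab)
}

#' Write a haplotype DAG as a tab-separated edge list
#'
#' @param dag a `haplotype_dag`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_dag <- function(dag, path) {
  tab <- dag_edge_table(dag)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Edge table of a DAG
#'
#' @param dag a `haplotype_dag`
#' @return data frame with columns child, parent, n_mutations (one row per
#'   edge; starting haplotypes have an empty parent)
#' @export
dag_edge_table <- function(dag) {
  rows <- lapply(dag$node_ids, function(id) {
    ps <- dag$parents[[id]]
    if (!length(ps))
      return(data.frame(child = id, parent = NA_character_, n_mutations = 1L))
    data.frame(child = id, parent = ps, n_mutations = dag$edge_mutations[[id]])
  })
  do.call(rbind, rows)
}

#' Read a haplotype-by-site allele matrix
#'
#' TSV with the haplotype id in the first column and one 0/1 column per site
#' (0 = ancestral/reference allele, 1 = alternative allele).
#'
#' @param path path to a TSV file
#' @return integer matrix with haplotype ids as row names and site ids as
#'   column names
#' @export
read_alleles <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  U <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(U) <- as.character(tab[[1L]])
  storage.mode(U) <- "integer"
  check_allele_matrix(U)
  U
}

#' Write a haplotype-by-site allele matrix
#'
#' @param U 0/1 matrix with haplotype row names
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_alleles <- function(U, path) {
  check_allele_matrix(U)
  tab <- data.frame(haplotype = rownames(U), U, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_allele_matrix <- function(U) {
  if (is.null(rownames(U))) stop("allele matrix must have haplotype row names")
  if (!all(U %in% c(0L, 1L))) stop("allele matrix entries must be 0/1")
  if (anyDuplicated(rownames(U))) stop("duplicated haplotype rows in allele matrix")
  invisible(U)
}

#' Export a sparse precision matrix in MatrixMarket coordinate format
#'
#' @param x an `hn_precision` object or a sparse Matrix
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_precision_mm <- function(x, path) {
  Q <- if (inherits(x, "hn_precision")) x$Q else x
  Matrix::writeMM(methods::as(Q, "generalMatrix"), path)
  invisible(path)
}
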