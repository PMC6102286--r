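#' Read a genes x samples expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; every
#' other cell must be numeric and finite.  Duplicate gene or sample ids and
#' empty data sections are rejected with informative errors.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) stop("empty data section in ", path, call. = FALSE)
  if (ncol(tab) < 2) stop("no sample columns in ", path, call. = FALSE)
  ids <- as.character(tab[[1]])
  not_num <- !vapply(tab[-1], is.numeric, logical(1))
  if (any(not_num)) {
    col <- names(tab[-1])[not_num][1]
    v <- suppressWarnings(as.numeric(tab[[col]]))
    line <- which(is.na(v))[1] + 1L
    stop("non-numeric cell in column '", col, "' (line ", line, ") of ", path,
         call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated gene id '", dup[1], "' (line ",
         which(ids == dup[1])[2] + 1L, ") in ", path, call. = FALSE)
  }
  if (anyDuplicated(names(tab)[-1])) {
    stop("duplicated sample ids in header of ", path, call. = FALSE)
  }
  m <- as.matrix(tab[, -1])
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-numeric or non-finite value at gene ", ids[bad[1]],
         ", sample ", colnames(m)[bad[2]], " in ", path, call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write a genes x samples matrix (or delta_expression) as TSV
#'
#' @param x Matrix or [delta_expression()].
#' @param path Output path.
#' @param id_column Name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "gene_id") {
  if (inherits(x, "delta_expression")) x <- x$values
  tab <- tibble::as_tibble(x, rownames = id_column)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Write a phenotype table as TSV
#'
#' @param phenotypes Phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' @param path TSV path with a `sample_id` column.
#' @return A tibble.
#' @export
read_phenotype_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop("phenotype table needs a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicated sample ids in ", path, call. = FALSE)
  }
  tab
}
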