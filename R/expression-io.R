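#' Read a genes-by-samples expression table
#'
#' Expression tables are tab-separated with a header row of sample identifiers
#' and gene symbols in the first column, the dialect of the TCGA
#' `unifiedScaled.txt`-style matrices of normalized mean fold inductions.
#'
#' @param path Path to a TSV file. The first header field is ignored (it names
#'   the gene column); remaining header fields are sample identifiers.
#' @param missing Token representing a missing value (default `"NA"`).
#' @param dedup Policy for duplicated gene symbols: `"error"` (default) fails
#'   loudly, `"first"` keeps the first occurrence of each symbol.
#' @return A tibble with character column `gene_id` followed by one numeric
#'   column per sample, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "TP53\t0.5\t-1.2", "EGFR\t1.1\t0.3"), tf)
#' read_expression_tsv(tf)
#' @export
read_expression_tsv <- function(path, missing = "NA", dedup = c("error", "first")) {
  dedup <- match.arg(dedup)
  if (!file.exists(path)) {
    topo_abort(paste0("file not found: ", path), "topo_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    topo_abort("empty file: no header row", "topo_error_parse")
  }
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != nfield[1])
  if (length(bad) > 0) {
    topo_abort(
      sprintf("malformed row: line %d has %d fields, expected %d",
              bad[1], nfield[bad[1]], nfield[1]),
      "topo_error_parse"
    )
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    topo_abort("duplicated sample identifiers in header", "topo_error_validation")
  }
  body <- lines[-1]
  if (length(body) == 0) {
    x <- tibble::as_tibble(c(
      list(gene_id = character(0)),
      stats::setNames(rep(list(double(0)), length(samples)), samples)
    ))
    return(validate_expression(x))
  }
  x <- suppressWarnings(readr::read_tsv(
    I(body),
    col_names = FALSE,
    na = missing,
    col_types = readr::cols(
      X1 = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    topo_abort(
      sprintf("parse error at line %d, column %d: expected %s, got '%s'",
              probs$row[1] + 1L, probs$col[1], probs$expected[1], probs$actual[1]),
      "topo_error_parse"
    )
  }
  names(x) <- c("gene_id", samples)
  if (anyDuplicated(x$gene_id)) {
    if (dedup == "error") {
      dups <- unique(x$gene_id[duplicated(x$gene_id)])
      topo_abort(
        paste0("duplicated gene symbols: ", paste(head(dups, 5), collapse = ", "),
               " (use dedup = \"first\" to keep first occurrences)"),
        "topo_error_validation"
      )
    }
    x <- x[!duplicated(x$gene_id), ]
  }
  validate_expression(x)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_tsv()]: `read_expression_tsv(write_expression_tsv(x, p))`
#' reproduces `x` exactly (doubles are written at full round-trip precision).
#'
#' @param x Expression tibble (`gene_id` column plus numeric sample columns).
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  x <- validate_expression(x)
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(x)
}

#' Validate an expression tibble
#'
#' Checks the contract shared by all downstream operations: a `gene_id`
#' character column without duplicates, unique sample names, and numeric
#' expression columns (missing values permitted).
#'
#' @param x A data frame to validate.
#' @return The validated tibble (invisibly coerced to tibble).
#' @export
validate_expression <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 1 || names(x)[1] != "gene_id") {
    topo_abort("expression data must be a data frame with first column 'gene_id'",
               "topo_error_validation")
  }
  x <- tibble::as_tibble(x)
  if (!is.character(x$gene_id)) {
    x$gene_id <- as.character(x$gene_id)
  }
  if (anyDuplicated(x$gene_id)) {
    topo_abort("duplicated gene identifiers", "topo_error_validation")
  }
  if (ncol(x) > 1 && anyDuplicated(names(x)[-1])) {
    topo_abort("duplicated sample identifiers", "topo_error_validation")
  }
  numeric_ok <- vapply(x[-1], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    topo_abort(
      paste0("non-numeric sample columns: ",
             paste(names(x)[-1][!numeric_ok], collapse = ", ")),
      "topo_error_validation"
    )
  }
  x
}

#' Read a gene annotation table
#'
#' Two-column TSV mapping gene symbols to chromosome labels, used to exclude
#' confounder gene groups (the sex-linked Y-chromosome block) from screening.
#'
#' @param path Path to a TSV with columns `gene_id` and `chromosome`.
#' @return A tibble with character columns `gene_id`, `chromosome`.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("gene_id", "chromosome") %in% names(ann))) {
    topo_abort("annotation must have columns 'gene_id' and 'chromosome'",
               "topo_error_validation")
  }
  ann[c("gene_id", "chromosome")]
}

#' Look up chromosomes for a set of genes
#'
#' Total over the requested genes: unannotated genes resolve to `"unknown"`.
#'
#' @param annotation Annotation tibble (`gene_id`, `chromosome`) or `NULL`.
#' @param genes Character vector of gene identifiers.
#' @return Character vector of chromosome labels, parallel to `genes`.
#' @export
annotation_lookup <- function(annotation, genes) {
  if (is.null(annotation)) {
    return(rep("unknown", length(genes)))
  }
  chr <- annotation$chromosome[match(genes, annotation$gene_id)]
  chr[is.na(chr)] <- "unknown"
  chr
}

#' Convert an expression tibble to a numeric matrix
#'
#' @param x Expression tibble (`gene_id` plus sample columns).
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
as_expression_matrix <- function(x) {
  x <- validate_expression(x)
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

## Row/column subsetting that preserves the order of the request and fails on
## unknown identifiers; the workhorse behind every "restrict to panel/cores" step.
select_genes <- function(x, genes) {
  miss <- setdiff(genes, x$gene_id)
  if (length(miss) > 0) {
    topo_abort(paste0("unknown genes: ", paste(head(miss, 5), collapse = ", ")),
               "topo_error_validation")
  }
  x[match(genes, x$gene_id), ]
}

select_samples <- function(x, samples) {
  miss <- setdiff(samples, names(x)[-1])
  if (length(miss) > 0) {
    topo_abort(paste0("unknown samples: ", paste(head(miss, 5), collapse = ", ")),
               "topo_error_validation")
  }
  x[c("gene_id", samples)]
}

sample_ids <- function(x) names(x)[-1]
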