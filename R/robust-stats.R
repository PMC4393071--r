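#' Nondimensionalized standard deviation of a sample
#'
#' A scale- and shift-invariant width statistic,
#' \deqn{\sigma = \mathrm{Var}(X) / (\mathbb{E}|X - \mathbb{E}[X]|)^2,}
#' computed with population (divide-by-n) moments. It is inspired by kurtosis
#' but far less tail-sensitive: its value is \eqn{\pi/2} for a Gaussian and 2
#' for a biexponential (Laplace) distribution, and drops well below \eqn{\pi/2}
#' for well-separated two-component mixtures, which makes small values a
#' screen for bimodally expressed genes.
#'
#' Extreme outliers more than `outlier_sd` standard deviations from the mean
#' are discarded in a single pass (mean and SD computed once on the non-missing
#' values) before the statistic is evaluated on the remainder.
#'
#' @param values Numeric vector; missing values are dropped first.
#' @param outlier_sd Positive multiple of the standard deviation beyond which
#'   values are discarded (default 8).
#' @return A one-row tibble with columns `sigma`, `n_used`, `n_discarded`.
#' @examples
#' sigma_stat(c(-1, -1, 1, 1)) # Var = 1, E|X - mu| = 1, sigma = 1
#' @export
sigma_stat <- function(values, outlier_sd = 8) {
  stopifnot(is.numeric(outlier_sd), length(outlier_sd) == 1, outlier_sd > 0)
  v <- values[is.finite(values)]
  if (length(v) < 3) {
    topo_abort("need at least 3 finite values to compute sigma",
               "topo_error_insufficient")
  }
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  keep <- abs(v - m) <= outlier_sd * s
  v2 <- v[keep]
  if (length(v2) < 3) {
    topo_abort("fewer than 3 values retained after outlier removal",
               "topo_error_insufficient")
  }
  m2 <- mean(v2)
  varp <- mean((v2 - m2)^2)
  mad <- mean(abs(v2 - m2))
  if (mad == 0) {
    topo_abort("sigma undefined: all retained values are identical",
               "topo_error_degenerate")
  }
  tibble::tibble(
    sigma = varp / mad^2,
    n_used = length(v2),
    n_discarded = length(v) - length(v2)
  )
}

#' Rank genes by the nondimensionalized standard deviation
#'
#' Computes [sigma_stat()] for every gene and orders the result ascending by
#' `sigma` -- the genes most likely to carry a bimodal (subtype-splitting)
#' expression pattern come first. Ties are broken by gene identifier; genes
#' whose statistic is undefined (too few values, or zero spread) are placed
#' last with `sigma = NA` and `defined = FALSE`.
#'
#' @param x Expression tibble (`gene_id` plus sample columns).
#' @param outlier_sd Outlier threshold passed to [sigma_stat()].
#' @return Tibble with columns `gene_id`, `sigma`, `n_used`, `n_discarded`,
#'   `defined`, `rank`, sorted ascending by `sigma`.
#' @export
sigma_ranking <- function(x, outlier_sd = 8) {
  x <- validate_expression(x)
  mat <- as_expression_matrix(x)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    res <- tryCatch(sigma_stat(mat[i, ], outlier_sd = outlier_sd),
                    topo_error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(gene_id = rownames(mat)[i], sigma = NA_real_,
                     n_used = NA_integer_, n_discarded = NA_integer_,
                     defined = FALSE)
    } else {
      dplyr::mutate(res, gene_id = rownames(mat)[i], defined = TRUE,
                    .before = 1)
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, !.data$defined, .data$sigma, .data$gene_id)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Correlation distance between two expression vectors
#'
#' \eqn{d(x, y) = 1 - C(x, y)} with \eqn{C} the Pearson correlation, the
#' standard genomic proximity; ranges over \[0, 2\] with 0 for perfectly
#' correlated and 2 for perfectly anticorrelated profiles. Missing values are
#' handled by pairwise-complete deletion.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single distance in \[0, 2\].
#' @examples
#' correlation_distance(c(1, 2, 3), c(1, 3, 2)) # 1 - 0.5
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) {
    topo_abort("vectors must have equal length", "topo_error_validation")
  }
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    topo_abort("need at least 3 pairwise-complete observations",
               "topo_error_insufficient")
  }
  x <- x[ok]
  y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    topo_abort("correlation distance undefined: zero variance input",
               "topo_error_degenerate")
  }
  clamp01_2(1 - cor(x, y))
}

clamp01_2 <- function(d) pmin(pmax(d, 0), 2)

#' Pairwise correlation distances over genes or samples
#'
#' Builds the full symmetric distance matrix used as input to the persistence
#' sweep. Items with zero variance (or fewer than 3 finite values) cannot be
#' placed in correlation space; they are excluded with a warning and listed in
#' the `"excluded"` attribute of the result.
#'
#' @param x Expression tibble.
#' @param axis `"genes"` (rows as points) or `"samples"` (columns as points).
#' @return Symmetric numeric matrix with zero diagonal, entries in \[0, 2\],
#'   dimnames naming the retained items; attribute `"excluded"` lists dropped
#'   items.
#' @export
pairwise_distances <- function(x, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  mat <- as_expression_matrix(validate_expression(x))
  if (axis == "samples") {
    mat <- t(mat)
  }
  usable <- apply(mat, 1, function(v) {
    v <- v[is.finite(v)]
    length(v) >= 3 && stats::var(v) > 0
  })
  excluded <- rownames(mat)[!usable]
  if (length(excluded) > 0) {
    rlang::warn(paste0("excluding ", length(excluded),
                       " zero-variance or data-poor item(s): ",
                       paste(head(excluded, 5), collapse = ", ")))
  }
  mat <- mat[usable, , drop = FALSE]
  if (nrow(mat) < 2) {
    topo_abort("fewer than 2 usable items for pairwise distances",
               "topo_error_insufficient")
  }
  C <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  if (anyNA(C)) {
    topo_abort("pairwise correlation undefined for some item pairs (too many missing values)",
               "topo_error_degenerate")
  }
  d <- clamp01_2(1 - C)
  diag(d) <- 0
  attr(d, "excluded") <- excluded
  d
}
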