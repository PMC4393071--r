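#' Build a simplicial complex from maximal simplices
#'
#' Stores an abstract simplicial complex explicitly, closed under faces: every
#' subset of a supplied simplex is added. Vertices may be given as character
#' identifiers or integers.
#'
#' @param maximal List of vertex vectors, one per (maximal) simplex. Faces are
#'   generated automatically.
#' @return A `simplicial_complex`: list with `vertices` (character ids) and
#'   `simplices`, a list whose element `k + 1` is an integer matrix with one
#'   row per `k`-simplex (columns are sorted vertex indices).
#' @examples
#' simplicial_complex(list(c("a", "b", "c"))) # a filled triangle
#' @export
simplicial_complex <- function(maximal) {
  stopifnot(is.list(maximal), length(maximal) > 0)
  verts <- sort(unique(as.character(unlist(maximal))))
  by_dim <- list()
  for (s in maximal) {
    s <- sort(unique(match(as.character(s), verts)))
    k <- length(s)
    for (m in seq_len(k)) {
      faces <- if (m == k) matrix(s, nrow = 1) else t(combn(s, m))
      key <- as.character(m)
      by_dim[[key]] <- rbind(by_dim[[key]], faces)
    }
  }
  dims <- sort(as.integer(names(by_dim)))
  simplices <- lapply(seq_len(max(dims)), function(m) {
    mat <- by_dim[[as.character(m)]]
    if (is.null(mat)) {
      return(matrix(integer(0), ncol = m))
    }
    mat <- unique(mat)
    mat[do.call(order, as.data.frame(mat)), , drop = FALSE]
  })
  structure(list(vertices = verts, simplices = simplices),
            class = "simplicial_complex")
}

#' @export
print.simplicial_complex <- function(x, ...) {
  counts <- vapply(x$simplices, nrow, integer(1))
  cat("Simplicial complex:",
      paste(sprintf("%d %d-simplices", counts, seq_along(counts) - 1),
            collapse = ", "), "\n")
  invisible(x)
}

n_simplices <- function(K, dim) {
  if (dim + 1 > length(K$simplices)) {
    return(0L)
  }
  nrow(K$simplices[[dim + 1]])
}

#' Vietoris-Rips (flag) complex of a point cloud
#'
#' Connects every pair of points at distance strictly below `r_c` and fills in
#' every clique of up to `max_dim + 1` vertices as a simplex: a `k`-simplex is
#' a set of `k + 1` points each pair of which is connected.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param r_c Cutoff radius (strict: edges require `d < r_c`).
#' @param max_dim Maximum simplex dimension, at most 3 (the pipeline needs
#'   components, loops, and voids only).
#' @return A `simplicial_complex`.
#' @export
rips_complex <- function(d, r_c, max_dim = 2) {
  if (inherits(d, "dist")) {
    d <- as.matrix(d)
  }
  stopifnot(is.matrix(d), nrow(d) == ncol(d), r_c >= 0)
  if (max_dim > 3 || max_dim < 0) {
    topo_abort("max_dim must be between 0 and 3", "topo_error_unsupported")
  }
  n <- nrow(d)
  verts <- rownames(d)
  if (is.null(verts)) {
    verts <- as.character(seq_len(n))
  }
  A <- d < r_c
  diag(A) <- FALSE
  simplices <- list(matrix(seq_len(n), ncol = 1))
  if (max_dim >= 1) {
    ut <- which(upper.tri(A) & A, arr.ind = TRUE)
    edges <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
    simplices[[2]] <- unname(edges)
  }
  if (max_dim >= 2 && nrow(simplices[[2]]) > 0) {
    tri <- list()
    for (e in seq_len(nrow(simplices[[2]]))) {
      i <- simplices[[2]][e, 1]
      j <- simplices[[2]][e, 2]
      common <- which(A[i, ] & A[j, ])
      common <- common[common > j]
      if (length(common) > 0) {
        tri[[length(tri) + 1]] <- cbind(i, j, common)
      }
    }
    simplices[[3]] <- if (length(tri) > 0) {
      m <- do.call(rbind, tri)
      unname(m[do.call(order, as.data.frame(m)), , drop = FALSE])
    } else {
      matrix(integer(0), ncol = 3)
    }
  } else if (max_dim >= 2) {
    simplices[[3]] <- matrix(integer(0), ncol = 3)
  }
  if (max_dim >= 3) {
    tet <- list()
    if (nrow(simplices[[3]]) > 0) {
      for (t3 in seq_len(nrow(simplices[[3]]))) {
        v <- simplices[[3]][t3, ]
        common <- which(A[v[1], ] & A[v[2], ] & A[v[3], ])
        common <- common[common > v[3]]
        if (length(common) > 0) {
          tet[[length(tet) + 1]] <- cbind(v[1], v[2], v[3], common)
        }
      }
    }
    simplices[[4]] <- if (length(tet) > 0) {
      m <- do.call(rbind, tet)
      unname(m[do.call(order, as.data.frame(m)), , drop = FALSE])
    } else {
      matrix(integer(0), ncol = 4)
    }
  }
  structure(list(vertices = verts, simplices = simplices),
            class = "simplicial_complex")
}

## Rank of a 0/1 matrix over GF(2) by Gaussian elimination with XOR row
## updates. Matrices here are small (boundary maps of desk-scale complexes),
## so a plain dense elimination is exact and fast enough.
gf2_rank <- function(M) {
  if (is.null(M) || length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) {
    return(0L)
  }
  M <- (M != 0)
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[row:nrow(M), col])
    if (length(piv) == 0) {
      next
    }
    piv <- piv[1] + row - 1L
    if (piv != row) {
      tmp <- M[row, ]
      M[row, ] <- M[piv, ]
      M[piv, ] <- tmp
    }
    hits <- which(M[, col])
    hits <- hits[hits != row]
    if (length(hits) > 0) {
      M[hits, ] <- xor(M[hits, , drop = FALSE],
                       matrix(M[row, ], nrow = length(hits),
                              ncol = ncol(M), byrow = TRUE))
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > nrow(M)) {
      break
    }
  }
  rank
}

## Boundary map from k-simplices to (k-1)-simplices over GF(2): entry (f, s)
## is 1 iff face f is a facet of simplex s.
boundary_matrix <- function(K, dim) {
  n_hi <- n_simplices(K, dim)
  n_lo <- n_simplices(K, dim - 1)
  if (dim == 0 || n_hi == 0 || n_lo == 0) {
    return(matrix(0L, nrow = max(n_lo, 0), ncol = n_hi))
  }
  hi <- K$simplices[[dim + 1]]
  lo <- K$simplices[[dim]]
  lo_key <- apply(lo, 1, paste, collapse = "-")
  B <- matrix(0L, nrow = n_lo, ncol = n_hi)
  for (s in seq_len(n_hi)) {
    for (drop in seq_len(dim + 1)) {
      face <- hi[s, -drop]
      f <- match(paste(face, collapse = "-"), lo_key)
      B[f, s] <- 1L
    }
  }
  B
}

#' Betti numbers of a simplicial complex over GF(2)
#'
#' Computes `b_i = (# i-simplices) - rank(boundary_i) - rank(boundary_{i+1})`
#' by exact rank reduction of the GF(2) boundary matrices: `b_0` counts
#' connected components, `b_1` independent loops, `b_2` enclosed voids. The
#' canonical checks: a figure-eight has `(b0, b1) = (1, 2)`, a triangulated
#' sphere `(1, 0, 1)`, and a triangulated torus `(1, 2, 1)`.
#'
#' @param K A [simplicial_complex()].
#' @param up_to Highest homology dimension to compute (default 2).
#' @return Named integer vector `b0`, `b1`, ... of length `up_to + 1`.
#' @examples
#' fig8 <- simplicial_complex(list(c(1, 2), c(2, 3), c(3, 1),
#'                                 c(1, 4), c(4, 5), c(5, 1)))
#' betti_numbers(fig8, up_to = 1) # c(b0 = 1, b1 = 2)
#' @export
betti_numbers <- function(K, up_to = 2) {
  stopifnot(inherits(K, "simplicial_complex"), up_to >= 0)
  ranks <- vapply(seq_len(up_to + 1), function(dim) {
    gf2_rank(boundary_matrix(K, dim))
  }, integer(1))
  betti <- vapply(0:up_to, function(i) {
    rank_lower <- if (i == 0) 0L else ranks[i]
    n_simplices(K, i) - rank_lower - ranks[i + 1]
  }, integer(1))
  stats::setNames(as.integer(betti), paste0("b", 0:up_to))
}

#' Euler characteristic of a simplicial complex
#'
#' The alternating sum of simplex counts; equals the alternating sum of Betti
#' numbers, a consistency check used throughout the test suite.
#'
#' @param K A [simplicial_complex()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(K) {
  counts <- vapply(K$simplices, nrow, integer(1))
  sum(counts * (-1)^(seq_along(counts) - 1))
}
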