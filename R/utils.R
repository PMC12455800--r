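
# Small shared helpers. Seeds are always scoped locally so library code never
# clobbers the caller's RNG stream.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Scaled cosine dissimilarity between two vectors
#'
#' `(1 - cos(a, b)) / 2`, mapping perfect agreement to 0, orthogonality to
#' 0.5 and opposition to 1. Used throughout the package to compare gene
#' embeddings.
#'
#' @param a,b Numeric vectors of equal length; neither may be all-zero.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' scaled_cosine_dissimilarity(c(1, 0), c(0, 1))  # 0.5
scaled_cosine_dissimilarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("scaled_cosine_dissimilarity: zero vector")
  (1 - sum(a * b) / (na * nb)) / 2
}

# Row-wise scaled cosine dissimilarity between each row of A and vector b,
# or between matched rows of A and B.
scaled_cosine_dissim_rows <- function(A, b) {
  if (is.matrix(b)) {
    num <- rowSums(A * b)
    den <- sqrt(rowSums(A^2)) * sqrt(rowSums(b^2))
  } else {
    num <- as.vector(A %*% b)
    den <- sqrt(rowSums(A^2)) * sqrt(sum(b^2))
  }
  if (any(den == 0)) stopf("scaled_cosine_dissimilarity: zero vector")
  (1 - num / den) / 2
}

# Robust dense/sparse -> dgCMatrix coercion (direct coercion from a base
# matrix is not guaranteed without Matrix attached).
as_sparse <- function(x) {
  if (inherits(x, "CsparseMatrix")) return(as(x, "generalMatrix"))
  as(as(Matrix::Matrix(as.matrix(x), sparse = TRUE), "CsparseMatrix"),
     "generalMatrix")
}

# Cosine similarity matrix between columns of a (possibly sparse) matrix.
cosine_cols <- function(M) {
  M <- as_sparse(M)
  nrm <- sqrt(Matrix::colSums(M^2))
  nrm[nrm == 0] <- 1
  Mn <- M %*% Matrix::Diagonal(x = 1 / nrm)
  as.matrix(Matrix::crossprod(Mn))
}

log_sum_exp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}
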