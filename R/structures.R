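#' RW1 precision structure matrix
#'
#' The tridiagonal structure matrix R of the first-order random walk, with
#' quadratic form x'Rx = sum (x[k+1] - x[k])^2. Its null space is the
#' constant vector, so the rank is n - 1.
#'
#' @param n length of the walk, at least 2.
#' @return sparse symmetric n x n [Matrix::Matrix].
#' @export
rw1_structure <- function(n) {
  if (n < 2) stop("RW1 structure needs n >= 2", call. = FALSE)
  d <- c(1, rep(2, n - 2), 1)
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(rep(-1, n - 1), d, rep(-1, n - 1)),
                     symmetric = FALSE)
}

#' ICAR precision structure matrix (graph Laplacian)
#'
#' Degree on the diagonal, -1 for every edge; quadratic form
#' x'Lx = sum over edges (x_i - x_j)^2. Rank is n minus the number of
#' connected components.
#'
#' @param graph a [region_graph()].
#' @return sparse symmetric [Matrix::Matrix].
#' @export
icar_structure <- function(graph) {
  n <- graph$n
  deg <- lengths(graph$nb)
  ii <- rep(seq_len(n), deg)
  jj <- unlist(graph$nb)
  if (length(ii) == 0)
    return(Matrix::Diagonal(n, 0))
  Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                       x = c(deg, rep(-1, length(ii))), dims = c(n, n))
}
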