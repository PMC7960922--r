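#' Weighted undirected graph
#'
#' Constructs the basic network object used throughout the package: a
#' symmetric nonnegative adjacency matrix with a zero diagonal. An entry of
#' exactly zero means "no edge"; nodes are indexed `1..n` at the R level.
#'
#' @param A numeric `n x n` adjacency matrix; must be symmetric (to `1e-10`
#'   absolute), with nonnegative entries and zero diagonal.
#' @param check logical; skip validation when `FALSE` (internal fast path).
#' @return An object of class `weighted_graph`: a list with elements `n`
#'   (node count) and `A` (the adjacency matrix).
#' @examples
#' g <- weighted_graph(matrix(c(0, 2, 2, 0), 2, 2))
#' strengths(g)
#' @export
weighted_graph <- function(A, check = TRUE) {
  A <- unname(as.matrix(A))
  storage.mode(A) <- "double"
  if (check) {
    if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
    if (anyNA(A)) stop("adjacency matrix contains missing values")
    if (any(A < 0)) stop("adjacency weights must be nonnegative")
    if (any(diag(A) != 0)) stop("self-loops are not allowed (nonzero diagonal)")
    if (max(abs(A - t(A))) > 1e-10) stop("adjacency matrix must be symmetric")
    A <- (A + t(A)) / 2  # exact symmetry after the tolerance check
  }
  structure(list(n = nrow(A), A = A), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes, %d edges, total weight %.6g\n",
              x$n, n_edges(x), total_weight(x)))
  invisible(x)
}

#' Node strengths, degrees, edge count, total weight
#'
#' Strength `s_i` is the sum of a node's edge weights (row sum of `A`);
#' degree `d_i` is its number of nonzero edges. `n_edges` counts unordered
#' connected pairs; `total_weight` is half the sum of all entries of `A`.
#'
#' @param g a [weighted_graph()].
#' @return `strengths`/`degrees`: numeric/integer vector of length `n`;
#'   `n_edges`/`total_weight`: a single number.
#' @export
strengths <- function(g) rowSums(g$A)

#' @rdname strengths
#' @export
degrees <- function(g) as.integer(rowSums(g$A > 0))

#' @rdname strengths
#' @export
n_edges <- function(g) sum(g$A > 0) / 2

#' @rdname strengths
#' @export
total_weight <- function(g) sum(g$A) / 2

#' Normalized graph Laplacian
#'
#' Computes `L = D^{-1/2} (D - A) D^{-1/2}` where `D` is the diagonal
#' strength matrix: off-diagonal entries are `-A_ij / sqrt(s_i s_j)` for
#' edges and the diagonal is 1 for nodes with positive strength. Isolated
#' nodes (`s_i = 0`) get an all-zero row and column, the matrix-product
#' convention under which no heat flows to or from them. Eigenvalues lie in
#' `[0, 2]`.
#'
#' @param g a [weighted_graph()].
#' @return A symmetric `n x n` matrix.
#' @export
normalized_laplacian <- function(g) {
  s <- strengths(g)
  isr <- ifelse(s > 0, 1 / sqrt(s), 0)
  L <- -g$A * outer(isr, isr)
  diag(L) <- ifelse(s > 0, 1, 0)
  L
}

#' Heat kernel of a weighted graph
#'
#' The heat kernel `h(tau) = exp(-tau * L)` quantifies the amount of heat
#' transferred between every pair of nodes after diffusing for time `tau`
#' under the normalized Laplacian `L`. It is symmetric with eigenvalues in
#' `(0, 1]` for `tau > 0` and equals the identity at `tau = 0`. Computed by
#' spectral decomposition (exact for a symmetric generator).
#'
#' @param g a [weighted_graph()].
#' @param tau nonnegative diffusion time (the rewiring interval).
#' @return An object of class `heat_kernel`: list with `H` (the `n x n`
#'   kernel matrix) and `tau`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' heat_kernel(g, 1)$H  # diagonal (1 + exp(-2))/2
#' @export
heat_kernel <- function(g, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0)
    stop("tau must be a single nonnegative number")
  e <- eigen(normalized_laplacian(g), symmetric = TRUE)
  H <- e$vectors %*% (exp(-tau * e$values) * t(e$vectors))
  H <- (H + t(H)) / 2
  structure(list(H = H, tau = tau), class = "heat_kernel")
}

#' @export
print.heat_kernel <- function(x, ...) {
  cat(sprintf("<heat_kernel> %d x %d, tau = %g\n", nrow(x$H), ncol(x$H), x$tau))
  invisible(x)
}

#' One row of the heat kernel
#'
#' Fast path used by the rewiring engine: returns `h(tau)[k, ]` only,
#' computed by the Taylor-series action of the matrix exponential (agrees
#' with [heat_kernel()] to machine precision).
#'
#' @inheritParams heat_kernel
#' @param k node index (1-based).
#' @return Numeric vector of length `n`.
#' @export
heat_kernel_row <- function(g, tau, k) {
  stopifnot(k >= 1, k <= g$n)
  if (tau < 0) stop("tau must be nonnegative")
  as.numeric(.heat_row_cpp(g$A, tau, as.integer(k) - 1L))
}
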