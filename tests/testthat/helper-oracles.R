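# Independent oracles and tiny fixture graphs used across the test files.

# truncated Taylor series for exp(-tau * L); independent of the package's
# spectral / series-action implementations
taylor_expm <- function(L, tau, terms = 50) {
  n <- nrow(L)
  acc <- diag(n)
  term <- diag(n)
  for (j in seq_len(terms)) {
    term <- term %*% (-tau * L) / j
    acc <- acc + term
  }
  acc
}

# naive O(n^2) double-loop evaluation of Newman's weighted modularity
modularity_bruteforce <- function(A, membership) {
  m2 <- sum(A)
  s <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + A[i, j] - s[i] * s[j] / m2
  q / m2
}

# enumerate all set partitions of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (l in seq_len(k + 1)) recurse(c(labels, l), max(k, l))
  }
  recurse(integer(0), 0L)
  out
}

# exhaustive-search optimum of modularity over every partition (n <= 8)
best_partition_q <- function(A) {
  max(vapply(all_partitions(nrow(A)),
             function(p) modularity_bruteforce(A, p), numeric(1)))
}

adjacency <- function(n, edges, w = 1) {
  A <- matrix(0, n, n)
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    wt <- if (length(w) == 1) w else w[i]
    A[e[1], e[2]] <- wt
    A[e[2], e[1]] <- wt
  }
  A
}

# path 1-2-3-4 with unit weights
path4 <- function() weighted_graph(adjacency(4, list(c(1, 2), c(2, 3), c(3, 4))))

triangle <- function(w = 1)
  weighted_graph(adjacency(3, list(c(1, 2), c(2, 3), c(1, 3)), w))

# two disconnected unit-weight triangles
two_triangles <- function()
  weighted_graph(adjacency(6, list(c(1, 2), c(2, 3), c(1, 3),
                                   c(4, 5), c(5, 6), c(4, 6))))

# hub = node 1
star <- function(n)
  weighted_graph(adjacency(n, lapply(2:n, function(j) c(1, j))))

random_small_graph <- function(n, p = 0.5, weighted = TRUE) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- ut[runif(length(ut)) < p]
  if (!length(on)) on <- sample(ut, 1)
  A[on] <- if (weighted) runif(length(on), 0.2, 2) else 1
  weighted_graph(A + t(A))
}
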