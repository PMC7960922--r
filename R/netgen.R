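#' Edge-weight distribution specification
#'
#' The two weight families studied: normal weights (default `mu = 1`,
#' `sigma = 0.25`), modelling the classical picture of presynaptic weights,
#' and lognormal weights (default `mu = 0`, `sigma = 1`), modelling the
#' right-skewed distributions reported for cortical synapses. After
#' sampling, weights are rescaled so their sum equals the number of edges
#' (see [sample_weights()]).
#'
#' @param family `"normal"` or `"lognormal"`.
#' @param mu location parameter (mean for normal; log-scale mean for
#'   lognormal).
#' @param sigma scale parameter, must be positive.
#' @return An object of class `weight_spec`.
#' @export
weight_spec <- function(family = c("normal", "lognormal"), mu = NULL, sigma = NULL) {
  family <- match.arg(family)
  if (is.null(mu)) mu <- if (family == "normal") 1 else 0
  if (is.null(sigma)) sigma <- if (family == "normal") 0.25 else 1
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu))
    stop("mu must be a single number")
  structure(list(family = family, mu = mu, sigma = sigma), class = "weight_spec")
}

#' Number of edges of the initial random network
#'
#' `m = round(2 ln(n) (n - 1))`, the edge budget that makes an
#' Erdos-Renyi `G(n, m)` network connected with overwhelming probability
#' (the density is well above the `ln(n)/n` connectivity threshold). At
#' `n = 100` this gives 912 edges, i.e. mean degree `2m/n = 18.24`.
#'
#' @param n node count, at least 2.
#' @return Integer edge count, at most `n(n-1)/2`.
#' @export
edge_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("n must be a single integer >= 2")
  m <- round(2 * log(n) * (n - 1))
  min(as.integer(m), as.integer(n * (n - 1) / 2))
}

#' Uniform random connected topology
#'
#' Draws `m` distinct unordered node pairs uniformly at random (`G(n, m)`)
#' and rejection-samples until the graph is connected. All edge weights are
#' a placeholder 1; see [generate_initial_network()] for weighted networks.
#'
#' @param n node count.
#' @param m edge count, at most `n(n-1)/2`.
#' @param max_tries resampling attempts before giving up (rejections are
#'   vanishingly rare at the default density).
#' @return A [weighted_graph()] with `m` unit-weight edges.
#' @export
random_topology <- function(n, m, max_tries = 1000) {
  max_m <- n * (n - 1) / 2
  if (m > max_m) stop("m exceeds the number of possible edges")
  if (m < 1) stop("m must be at least 1")
  ut <- which(upper.tri(matrix(0, n, n)))
  for (i in seq_len(max_tries)) {
    A <- matrix(0, n, n)
    A[sample(ut, m)] <- 1
    A <- A + t(A)
    if (is_connected_adjacency(A)) return(weighted_graph(A, check = FALSE))
  }
  stop("failed to draw a connected topology; increase m or max_tries")
}

# breadth-first connectivity check on an adjacency matrix
is_connected_adjacency <- function(A) {
  n <- nrow(A)
  if (n == 1) return(TRUE)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Sample and normalize edge weights
#'
#' Draws `m` weights from the given family and rescales them so their sum
#' equals `m` exactly, matching the convention that the total weight of the
#' network equals its number of connections. Nonpositive normal draws are
#' redrawn (probability about `3e-5` at the default `mu = 1`,
#' `sigma = 0.25`, so the sampling distribution is essentially unchanged
#' while no edge is ever silently deleted).
#'
#' @param spec a [weight_spec()].
#' @param m number of weights, at least 1.
#' @return Numeric vector of `m` positive weights summing to `m`.
#' @export
sample_weights <- function(spec, m) {
  if (!inherits(spec, "weight_spec")) stop("spec must be a weight_spec")
  if (m < 1) stop("m must be at least 1")
  w <- switch(spec$family,
    normal = {
      x <- rnorm(m, spec$mu, spec$sigma)
      while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), spec$mu, spec$sigma)
      x
    },
    lognormal = rlnorm(m, spec$mu, spec$sigma)
  )
  w * (m / sum(w))
}

#' Generate an initial weighted random network
#'
#' Composes [edge_count()], [random_topology()] and [sample_weights()]:
#' a connected `G(n, m)` topology with `m = round(2 ln(n) (n - 1))` edges
#' whose weights are drawn from `spec` and normalized to total weight `m`.
#'
#' @param n node count.
#' @param spec a [weight_spec()]; default normal weights.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the network is fully reproducible.
#' @return A [weighted_graph()].
#' @examples
#' g <- generate_initial_network(100, weight_spec("normal"), seed = 1)
#' n_edges(g)       # 912
#' total_weight(g)  # 912
#' @export
generate_initial_network <- function(n, spec = weight_spec("normal"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- edge_count(n)
  g <- random_topology(n, m)
  w <- sample_weights(spec, m)
  idx <- which(upper.tri(g$A) & g$A > 0)
  A <- matrix(0, n, n)
  A[idx] <- w
  A <- A + t(A)
  weighted_graph(A, check = FALSE)
}
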