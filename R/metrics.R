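#' Weighted modularity of a partition
#'
#' Newman's modularity
#' `Q = 1/(2m) * sum_ij (A_ij - s_i s_j / (2m)) * delta(c_i, c_j)`,
#' where `m` is the total weight of the network (equal to the edge count
#' here, because initial weights are normalized to sum to the edge count
#' and rewiring conserves both). Dense within-community and sparse
#' between-community wiring gives large `Q`.
#'
#' @param g a [weighted_graph()].
#' @param membership integer community label per node (length `n`).
#' @return Modularity `Q` in `[-1, 1]`.
#' @export
modularity <- function(g, membership) {
  if (length(membership) != g$n)
    stop("membership must have one label per node")
  m2 <- sum(g$A)  # 2m
  if (m2 <= 0) stop("graph has no weight")
  s <- strengths(g)
  labs <- unique(membership)
  q <- 0
  for (l in labs) {
    idx <- which(membership == l)
    q <- q + sum(g$A[idx, idx]) / m2 - (sum(s[idx]) / m2)^2
  }
  q
}

#' Multilevel community detection
#'
#' Assigns nodes to communities with the multilevel (Louvain) greedy
#' modularity-maximization heuristic, as implemented in igraph, and
#' reports the partition's modularity evaluated by [modularity()].
#'
#' @param g a [weighted_graph()].
#' @param seed optional integer seed for the heuristic's randomized
#'   sweep order.
#' @return A list of class `partition_result`: `membership` (integer
#'   labels) and `Q`.
#' @export
detect_communities <- function(g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ig <- igraph::graph_from_adjacency_matrix(g$A, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_louvain(ig, resolution = 1)
  mem <- as.integer(igraph::membership(cl))
  structure(list(membership = mem, Q = modularity(g, mem)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %d communities, Q = %.4f\n",
              length(unique(x$membership)), x$Q))
  invisible(x)
}

#' Degree-outlier rule against a Poisson baseline
#'
#' For an Erdos-Renyi random network the degree distribution is well
#' approximated by a Poisson with mean `<k>` and dispersion
#' `sigma_k = sqrt(<k>)`. A node is an outlier when its degree falls
#' strictly outside `<k> +/- 3 sigma_k`. Modular networks have almost no
#' outliers (degrees hug the mean); centralized ones have many (sparse
#' majority plus heavily connected hubs).
#'
#' @param k_mean reference mean degree `<k>`; defaults in
#'   [outlier_proportion()] to the network's own `2m/n`.
#' @return `outlier_spec`: list with `k_mean`, `sigma_k`, `lower`, `upper`.
#' @export
outlier_spec <- function(k_mean) {
  if (!is.numeric(k_mean) || length(k_mean) != 1 || k_mean <= 0)
    stop("k_mean must be a single positive number")
  sigma_k <- sqrt(k_mean)
  structure(list(k_mean = k_mean, sigma_k = sigma_k,
                 lower = k_mean - 3 * sigma_k, upper = k_mean + 3 * sigma_k),
            class = "outlier_spec")
}

#' @rdname outlier_spec
#' @param g a [weighted_graph()].
#' @param spec an [outlier_spec()]; by default derived from `g`'s own mean
#'   degree.
#' @return `outlier_proportion`: fraction of nodes in `[0, 1]` with degree
#'   strictly outside the band.
#' @export
outlier_proportion <- function(g, spec = NULL) {
  if (is.null(spec)) spec <- outlier_spec(2 * n_edges(g) / g$n)
  d <- degrees(g)
  mean(d < spec$lower | d > spec$upper)
}

#' Classify a network as modular, intermediate or centralized
#'
#' Low modularity marks centralized topologies (hub-dominated), high
#' modularity marks modular ones; the band between the thresholds is the
#' grey zone around the phase transition where either label is defensible
#' (the defaults 0.45 / 0.50 bracket the mean transition-point modularity
#' of the two weight families).
#'
#' @param Q modularity value(s).
#' @param t_low,t_high ordered thresholds.
#' @return Character vector: `"centralized"`, `"intermediate"` or
#'   `"modular"`.
#' @export
classify_topology <- function(Q, t_low = 0.45, t_high = 0.50) {
  if (t_low > t_high) stop("thresholds must satisfy t_low <= t_high")
  ifelse(Q < t_low, "centralized", ifelse(Q > t_high, "modular", "intermediate"))
}

#' Pooled degree / strength distributions
#'
#' Pools node degrees (or strengths, binned) across a list of networks and
#' normalizes the counts so the proportions sum to 1.
#'
#' @param graphs nonempty list of [weighted_graph()]s.
#' @return Data frame with columns `value` and `proportion`.
#' @export
degree_histogram <- function(graphs) {
  if (!length(graphs)) stop("need at least one graph")
  d <- unlist(lapply(graphs, degrees))
  tab <- table(d)
  data.frame(value = as.numeric(names(tab)),
             proportion = as.numeric(tab) / length(d))
}

#' @rdname degree_histogram
#' @param breaks passed to [hist()]-style binning via [cut()]; either a
#'   number of bins or a vector of break points.
#' @export
strength_histogram <- function(graphs, breaks = 30) {
  if (!length(graphs)) stop("need at least one graph")
  s <- unlist(lapply(graphs, strengths))
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  data.frame(value = h$mids, proportion = h$counts / sum(h$counts))
}
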