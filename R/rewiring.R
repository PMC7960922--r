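#' Rewiring run configuration
#'
#' Bundles the control parameters of one adaptive rewiring run: the
#' rewiring interval `tau` (the diffusion time of the heat kernel before
#' each rewiring decision — the model's single control parameter), the
#' probability `p_random` of performing a uniformly random rewiring instead
#' of a diffusion-guided one, the number of rewiring steps `r`, and an
#' optional RNG seed.
#'
#' @param tau positive rewiring interval.
#' @param p_random probability in `[0, 1]` of a random rewiring step.
#' @param r number of rewiring steps (nonnegative integer).
#' @param seed optional integer seed; when given, [run_rewiring()] calls
#'   `set.seed(seed)` before the run.
#' @param snapshot_every optional positive integer: keep a copy of the
#'   adjacency matrix every that many steps (0 = no snapshots).
#' @return An object of class `rewiring_config`.
#' @export
rewiring_config <- function(tau, p_random = 0.2, r = 4000, seed = NULL,
                            snapshot_every = 0) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0)
    stop("tau must be a single positive number")
  if (!is.numeric(p_random) || p_random < 0 || p_random > 1)
    stop("p_random must lie in [0, 1]")
  if (!is.numeric(r) || r < 0 || r != round(r))
    stop("r must be a nonnegative integer")
  if (snapshot_every < 0 || snapshot_every != round(snapshot_every))
    stop("snapshot_every must be a nonnegative integer")
  structure(list(tau = tau, p_random = p_random, r = as.integer(r),
                 seed = seed, snapshot_every = as.integer(snapshot_every)),
            class = "rewiring_config")
}

#' Select a rewiring pivot node
#'
#' Draws a node `k` uniformly from the eligible set
#' `{k : 0 < d_k < n - 1}`: nodes with at least one edge that are not
#' connected to everything. Consumes one draw from R's RNG stream.
#'
#' @param g a [weighted_graph()].
#' @return A 1-based node index.
#' @export
select_pivot <- function(g) {
  k <- .select_pivot_cpp(g$A)
  if (k < 0)
    stop(rewiring_impossible_condition(g))
  k + 1L
}

rewiring_impossible_condition <- function(g) {
  structure(class = c("rewiring_impossible", "error", "condition"),
            list(message = paste0(
                   "no eligible pivot: every node has degree 0 or n - 1 (n = ",
                   g$n, ")"),
                 call = NULL))
}

#' Diffusion-guided candidate pair
#'
#' For pivot `k`, computes the heat kernel of the current adjacency matrix
#' and returns `j1`, the non-neighbour with the highest heat transfer
#' `h(tau)[k, j]`, and `j2`, the neighbour with the lowest. Exact ties
#' (within `1e-12` relative) are broken uniformly at random.
#'
#' @param g a [weighted_graph()].
#' @param tau rewiring interval.
#' @param k pivot node (1-based) with `0 < d_k < n - 1`.
#' @return Integer vector `c(j1, j2)` (1-based).
#' @export
diffusion_candidates <- function(g, tau, k) {
  .candidates_cpp(g$A, tau, as.integer(k) - 1L, FALSE) + 1L
}

#' Uniformly random candidate pair
#'
#' `j1` is drawn uniformly from the non-neighbours of `k` (excluding `k`),
#' `j2` uniformly from its neighbours.
#'
#' @inheritParams diffusion_candidates
#' @return Integer vector `c(j1, j2)` (1-based).
#' @export
random_candidates <- function(g, k) {
  .candidates_cpp(g$A, 0, as.integer(k) - 1L, TRUE) + 1L
}

#' One adaptive rewiring step
#'
#' Selects a pivot `k`, then with probability `p_random` chooses the
#' candidate pair at random (otherwise by heat diffusion), deletes the edge
#' `(k, j2)` and adds `(k, j1)` carrying the deleted edge's weight. Edge
#' count, total weight and the multiset of edge weights are invariant.
#'
#' @param g a [weighted_graph()].
#' @param cfg a [rewiring_config()] (its `r` is ignored; one step is taken).
#' @return The rewired [weighted_graph()].
#' @export
rewire_step <- function(g, cfg) {
  res <- run_rewiring(g, rewiring_config(cfg$tau, cfg$p_random, r = 1,
                                         seed = cfg$seed))
  if (!res$completed) stop(rewiring_impossible_condition(g))
  res$graph
}

#' Run the adaptive rewiring algorithm
#'
#' Applies `cfg$r` rewiring steps to `g0` with a single RNG stream;
#' the pair (input graph, config incl. seed) fully determines the
#' trajectory. If at some step no eligible pivot exists (e.g. the graph has
#' become complete or empty at every node) the run stops early and the
#' partial result is returned with `completed = FALSE`.
#'
#' @param g0 initial [weighted_graph()].
#' @param cfg a [rewiring_config()].
#' @return A list of class `rewiring_result`: `graph` (final
#'   [weighted_graph()]), `steps_done`, `completed`, `snapshots` (list of
#'   [weighted_graph()]s) and `snapshot_steps`.
#' @examples
#' g <- generate_initial_network(20, seed = 1)
#' res <- run_rewiring(g, rewiring_config(tau = 2, r = 100, seed = 1))
#' res$completed
#' @export
run_rewiring <- function(g0, cfg) {
  stopifnot(inherits(g0, "weighted_graph"), inherits(cfg, "rewiring_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- .rewire_run_cpp(g0$A, cfg$tau, cfg$p_random, cfg$r, cfg$snapshot_every)
  structure(list(graph = weighted_graph(out$A, check = FALSE),
                 steps_done = out$steps_done,
                 completed = out$completed,
                 snapshots = lapply(out$snapshots, weighted_graph, check = FALSE),
                 snapshot_steps = as.integer(out$snapshot_steps)),
            class = "rewiring_result")
}

#' @export
print.rewiring_result <- function(x, ...) {
  cat(sprintf("<rewiring_result> %d steps%s, %d snapshots\n",
              x$steps_done,
              if (x$completed) "" else " (terminated early: no eligible pivot)",
              length(x$snapshots)))
  invisible(x)
}
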