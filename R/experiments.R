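#' Deterministic replicate seeds
#'
#' Derives an integer seed below `2^31` from a master seed and an arbitrary
#' label (e.g. tau value and replicate index) by a small polynomial string
#' hash, so that every replicate of every experiment is independently
#' reproducible from the master seed alone.
#'
#' @param master master integer seed.
#' @param ... further components (numbers or strings) identifying the
#'   replicate.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

new_network <- function(family, n) {
  generate_initial_network(n, weight_spec(family))
}

#' Sweep the rewiring interval
#'
#' For every `tau` on the grid, generates `reps` fresh random networks
#' (derived seeds), rewires each for `r` steps, and records the final
#' modularity (multilevel detection), degree-outlier proportion and
#' topology class. Replicates that terminate early are recorded with
#' `completed = FALSE` and excluded from the aggregates.
#'
#' @param family `"normal"` or `"lognormal"` edge weights.
#' @param p_random probability of a random rewiring step.
#' @param tau_grid strictly increasing vector of rewiring intervals.
#' @param reps replicates per grid point (at least 2).
#' @param r rewiring steps per replicate.
#' @param seed master seed.
#' @param n node count.
#' @return A list of class `tau_sweep`: `data` (one row per replicate:
#'   `tau`, `rep`, `Q`, `outliers`, `class`, `completed`) and `summary`
#'   (per-tau mean/sd of `Q` and outlier proportion).
#' @export
tau_sweep <- function(family, p_random, tau_grid, reps, r, seed, n = 100) {
  if (reps < 2) stop("need at least 2 replicates per grid point")
  if (is.unsorted(tau_grid, strictly = TRUE))
    stop("tau_grid must be strictly increasing")
  rows <- vector("list", length(tau_grid) * reps)
  i <- 0
  for (tau in tau_grid) {
    for (rep in seq_len(reps)) {
      i <- i + 1
      s <- derive_seed(seed, "sweep", family, tau, rep)
      set.seed(s)
      g <- new_network(family, n)
      res <- run_rewiring(g, rewiring_config(tau, p_random, r))
      Q <- detect_communities(res$graph)$Q
      rows[[i]] <- data.frame(tau = tau, rep = rep, Q = Q,
                              outliers = outlier_proportion(res$graph),
                              class = classify_topology(Q),
                              completed = res$completed)
    }
  }
  data <- do.call(rbind, rows)
  ok <- data[data$completed, ]
  agg <- do.call(rbind, lapply(split(ok, ok$tau), function(d) {
    data.frame(tau = d$tau[1], mean_Q = mean(d$Q), sd_Q = sd(d$Q),
               mean_outliers = mean(d$outliers), sd_outliers = sd(d$outliers),
               reps = nrow(d))
  }))
  rownames(agg) <- NULL
  structure(list(data = data, summary = agg, family = family,
                 p_random = p_random, r = r, seed = seed, n = n),
            class = "tau_sweep")
}

#' @export
print.tau_sweep <- function(x, ...) {
  cat(sprintf("<tau_sweep> family = %s, p_random = %g, r = %d, %d grid points x %d reps\n",
              x$family, x$p_random, x$r, nrow(x$summary), max(x$data$rep)))
  print(x$summary)
  invisible(x)
}

#' Locate the transition point of a response curve
#'
#' Returns the grid `tau` with the largest finite-difference derivative
#' magnitude: the inflection point of the sigmoidal outlier-proportion
#' curve (`mode = "ascending_sigmoid"`, largest positive derivative) or
#' the steepest drop of the modularity curve
#' (`mode = "descending_segment"`, largest `|derivative|` restricted to
#' where the curve decreases). Central differences are used at interior
#' points and one-sided differences at the ends; ties resolve to the
#' smallest `tau`, and a curve with constant derivative triggers a
#' warning. No sub-grid interpolation is attempted, so the grid spacing
#' bounds the precision of the estimate.
#'
#' @param tau_grid strictly increasing grid.
#' @param mean_curve response values on the grid (same length).
#' @param mode `"ascending_sigmoid"` or `"descending_segment"`.
#' @return The transition `tau` (a grid point), with attribute
#'   `"derivative"` holding the full derivative vector.
#' @export
find_transition <- function(tau_grid, mean_curve,
                            mode = c("ascending_sigmoid", "descending_segment")) {
  mode <- match.arg(mode)
  k <- length(tau_grid)
  if (k < 3) stop("need at least 3 grid points")
  if (length(mean_curve) != k) stop("curve and grid lengths differ")
  if (is.unsorted(tau_grid, strictly = TRUE))
    stop("tau_grid must be strictly increasing")
  deriv <- numeric(k)
  deriv[1] <- (mean_curve[2] - mean_curve[1]) / (tau_grid[2] - tau_grid[1])
  deriv[k] <- (mean_curve[k] - mean_curve[k - 1]) / (tau_grid[k] - tau_grid[k - 1])
  if (k > 2) {
    idx <- 2:(k - 1)
    deriv[idx] <- (mean_curve[idx + 1] - mean_curve[idx - 1]) /
      (tau_grid[idx + 1] - tau_grid[idx - 1])
  }
  scale <- max(abs(deriv))
  if (scale == 0)
    stop("no transition: the curve is constant")
  if (diff(range(deriv)) <= 1e-12 * max(1, scale))
    warning("derivative is constant across the grid; tie broken at the smallest tau")
  score <- switch(mode,
    ascending_sigmoid = deriv,
    descending_segment = ifelse(deriv < 0, -deriv, -Inf))
  if (all(!is.finite(score)))
    stop("no transition: the curve has no descending segment")
  tau_star <- tau_grid[which.max(score)]  # first max = smallest tau on ties
  attr(tau_star, "derivative") <- deriv
  tau_star
}

#' Final-modularity distributions near the transition
#'
#' For each `tau` in `tau_list`, runs `reps` independent rewiring
#' replicates and returns every final modularity value, suitable for
#' histogramming the perturbation response at
#' `tau_transition + c(-2, -1, 0, 1, 2) * delta_tau`.
#'
#' @inheritParams tau_sweep
#' @param tau_list tau values (need not be a grid).
#' @return Data frame with columns `tau`, `rep`, `Q`, `class`.
#' @export
modularity_distributions <- function(family, tau_list, reps, r, seed,
                                     n = 100, p_random = 0.2) {
  if (reps < 2) stop("need at least 2 replicates")
  rows <- vector("list", length(tau_list) * reps)
  i <- 0
  for (tau in tau_list) {
    for (rep in seq_len(reps)) {
      i <- i + 1
      set.seed(derive_seed(seed, "perturb", family, tau, rep))
      g <- new_network(family, n)
      res <- run_rewiring(g, rewiring_config(tau, p_random, r))
      Q <- detect_communities(res$graph)$Q
      rows[[i]] <- data.frame(tau = tau, rep = rep, Q = Q,
                              class = classify_topology(Q))
    }
  }
  do.call(rbind, rows)
}

#' Correlation between initial and rewired modularity
#'
#' Measures how much of the variability of rewired networks is inherited
#' from chance biases of the initial random network: per replicate, the
#' modularity of the fresh random network and of the same network after
#' `r` rewirings at `tau` are recorded, and their Pearson correlation is
#' returned along with the OLS line through the pairs.
#'
#' @inheritParams tau_sweep
#' @param tau rewiring interval.
#' @return A list of class `initial_final_correlation`: `rho`, `pairs`
#'   (data frame `Q_initial`, `Q_final`), `fit` (`alpha`, `beta`).
#' @export
initial_final_correlation <- function(family, tau, reps, r, seed,
                                      n = 100, p_random = 0.2) {
  if (reps < 3) stop("need at least 3 replicates")
  qi <- qf <- numeric(reps)
  for (rep in seq_len(reps)) {
    set.seed(derive_seed(seed, "corr", family, tau, rep))
    g <- new_network(family, n)
    qi[rep] <- detect_communities(g)$Q
    res <- run_rewiring(g, rewiring_config(tau, p_random, r))
    qf[rep] <- detect_communities(res$graph)$Q
  }
  if (sd(qi) == 0 || sd(qf) == 0)
    stop("correlation undefined: zero variance on one side")
  fit <- linear_fit(qi, qf)
  structure(list(rho = cor(qi, qf),
                 pairs = data.frame(Q_initial = qi, Q_final = qf),
                 fit = fit, tau = tau, family = family),
            class = "initial_final_correlation")
}

#' @export
print.initial_final_correlation <- function(x, ...) {
  cat(sprintf("<initial_final_correlation> %s, tau = %g: rho = %.3f (n = %d)\n",
              x$family, x$tau, x$rho, nrow(x$pairs)))
  invisible(x)
}

#' Two-stage rewiring experiment
#'
#' Probes specificity versus robustness on networks with an established
#' (non-random) connectivity pattern. Per replicate: a fresh random network
#' is rewired `r1` times at `tau_transition` (where final topologies span
#' the full modular-to-centralized range), its modularity `Q_4000` is
#' recorded, and the network is then rewired a further `r2` times at each
#' `tau_test`, giving `Q_8000`. The line `Q_8000 = alpha * Q_4000 + beta`
#' is fitted by least squares per `tau_test`; a near-diagonal fit marks
#' robustness, a near-horizontal fit specificity, and a low squared
#' Pearson correlation marks flexibility. Stage-1 trajectories are shared
#' across `tau_test` values (each continuation reseeds its own stream).
#'
#' @inheritParams tau_sweep
#' @param tau_transition stage-1 rewiring interval.
#' @param tau_test stage-2 interval(s); may be a vector.
#' @param r1,r2 rewiring steps in each stage.
#' @return A list of class `two_stage_result`: `pairs` (data frame
#'   `tau_test`, `rep`, `Q_initial`, `Q_4000`, `Q_8000`) and `fits` (data
#'   frame `tau_test`, `alpha`, `beta`, `r2`, with `r2` the squared
#'   Pearson correlation).
#' @export
two_stage <- function(family, tau_transition, tau_test, reps,
                      r1 = 4000, r2 = 4000, seed = 0, n = 100,
                      p_random = 0.2) {
  if (reps < 3) stop("need at least 3 replicates")
  stage1 <- vector("list", reps)
  q0 <- q1 <- numeric(reps)
  for (rep in seq_len(reps)) {
    set.seed(derive_seed(seed, "stage1", family, tau_transition, rep))
    g <- new_network(family, n)
    q0[rep] <- detect_communities(g)$Q
    res <- run_rewiring(g, rewiring_config(tau_transition, p_random, r1))
    stage1[[rep]] <- res$graph
    q1[rep] <- detect_communities(res$graph)$Q
  }
  pairs <- do.call(rbind, lapply(tau_test, function(tt) {
    q2 <- numeric(reps)
    for (rep in seq_len(reps)) {
      set.seed(derive_seed(seed, "stage2", family, tt, rep))
      res <- run_rewiring(stage1[[rep]], rewiring_config(tt, p_random, r2))
      q2[rep] <- detect_communities(res$graph)$Q
    }
    data.frame(tau_test = tt, rep = seq_len(reps),
               Q_initial = q0, Q_4000 = q1, Q_8000 = q2)
  }))
  fits <- do.call(rbind, lapply(split(pairs, pairs$tau_test), function(d) {
    f <- linear_fit(d$Q_4000, d$Q_8000)
    data.frame(tau_test = d$tau_test[1], alpha = f[["alpha"]],
               beta = f[["beta"]], r2 = r_squared(d$Q_4000, d$Q_8000))
  }))
  rownames(fits) <- NULL
  structure(list(pairs = pairs, fits = fits, family = family,
                 tau_transition = tau_transition, r1 = r1, r2 = r2,
                 seed = seed, n = n, p_random = p_random),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf("<two_stage_result> %s, stage 1 at tau = %g, %d replicates\n",
              x$family, x$tau_transition, max(x$pairs$rep)))
  print(x$fits)
  invisible(x)
}

#' Ordinary least-squares line
#'
#' Slope and intercept of the least-squares line `y = alpha * x + beta`.
#'
#' @param x,y numeric vectors of equal length (at least 2 points; `x` not
#'   constant).
#' @return Named numeric vector `c(alpha = slope, beta = intercept)`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need >= 2 paired points")
  if (sd(x) == 0) stop("x is constant: slope undefined")
  co <- coef(lm(y ~ x))
  c(alpha = unname(co[2]), beta = unname(co[1]))
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length, both non-constant.
#' @return `R^2` in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need >= 2 paired points")
  if (sd(x) == 0 || sd(y) == 0) stop("R^2 undefined: zero variance")
  cor(x, y)^2
}

#' Bootstrap distribution of R-squared
#'
#' Resamples `sample_size` pairs with replacement from a pool of
#' `pool_size` pairs (subsampled without replacement if more are supplied),
#' computes the squared Pearson correlation for each resample, and returns
#' its bootstrap mean and standard deviation — the flexibility summary of
#' a two-stage experiment.
#'
#' @param pairs two-column matrix or data frame of `(Q_4000, Q_8000)`
#'   pairs.
#' @param sample_size pairs drawn per bootstrap resample.
#' @param pool_size pool the resamples are drawn from.
#' @param reps_boot number of bootstrap resamples.
#' @param seed optional integer seed.
#' @param strict if `TRUE`, fewer than `pool_size` supplied pairs is an
#'   error; otherwise the available pairs are used with a warning.
#' @return List with `mean`, `sd` and the vector of `values`.
#' @export
bootstrap_r2 <- function(pairs, sample_size = 100, pool_size = 200,
                         reps_boot = 1000, seed = NULL, strict = FALSE) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  if (!is.null(seed)) set.seed(seed)
  if (nrow(pairs) < pool_size) {
    if (strict) stop(sprintf("need at least %d pairs, got %d",
                             pool_size, nrow(pairs)))
    warning(sprintf("pool has %d < %d pairs; using all of them",
                    nrow(pairs), pool_size))
  } else if (nrow(pairs) > pool_size) {
    pairs <- pairs[sample(nrow(pairs), pool_size), , drop = FALSE]
  }
  vals <- vapply(seq_len(reps_boot), function(i) {
    idx <- sample(nrow(pairs), sample_size, replace = TRUE)
    r_squared(pairs[idx, 1], pairs[idx, 2])
  }, numeric(1))
  list(mean = mean(vals), sd = sd(vals), values = vals)
}
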