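#' Read a weighted graph from disk
#'
#' Two plain-text formats are supported: a weighted edge list
#' (`edge_tsv`: three tab-separated columns `u`, `v`, `w`, 0-based integer
#' node ids, one undirected edge per line with `u < v`) and a dense
#' adjacency matrix (`adjacency_csv`: `n` lines of `n` comma-separated
#' decimals). Self-loops, negative weights, duplicate or asymmetric
#' entries are rejected with the offending line number.
#'
#' @param path file to read.
#' @param format `"edge_tsv"` or `"adjacency_csv"`; guessed from the file
#'   extension (`.tsv` / `.csv`) when omitted.
#' @param n_nodes for `edge_tsv`, the node count; defaults to
#'   `max(node id) + 1`.
#' @return A [weighted_graph()].
#' @export
read_graph <- function(path, format = NULL, n_nodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- guess_format(path, format)
  if (format == "edge_tsv") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("u", "v", "w"),
                     colClasses = c("integer", "integer", "numeric"))
    if (!nrow(df)) stop("empty edge list: ", path)
    for (i in seq_len(nrow(df))) {
      if (df$u[i] == df$v[i])
        stop(sprintf("%s line %d: self-loop (%d, %d)", path, i, df$u[i], df$v[i]))
      if (df$u[i] > df$v[i])
        stop(sprintf("%s line %d: expected u < v, got (%d, %d)",
                     path, i, df$u[i], df$v[i]))
      if (df$w[i] < 0)
        stop(sprintf("%s line %d: negative weight %g", path, i, df$w[i]))
    }
    if (anyDuplicated(df[c("u", "v")]))
      stop(sprintf("%s line %d: duplicate edge",
                   path, anyDuplicated(df[c("u", "v")])))
    n <- if (is.null(n_nodes)) max(df$v) + 1L else as.integer(n_nodes)
    A <- matrix(0, n, n)
    A[cbind(df$u + 1L, df$v + 1L)] <- df$w
    A <- A + t(A)
    weighted_graph(A)
  } else {
    A <- as.matrix(read.table(path, sep = ",", header = FALSE))
    if (nrow(A) != ncol(A)) stop(path, ": adjacency matrix is not square")
    bad <- which(abs(A - t(A)) > 1e-10, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("%s line %d: asymmetric entry at column %d",
                   path, bad[1, 1], bad[1, 2]))
    bad <- which(A < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("%s line %d: negative weight at column %d",
                   path, bad[1, 1], bad[1, 2]))
    bad <- which(diag(A) != 0)
    if (length(bad))
      stop(sprintf("%s line %d: self-loop on the diagonal", path, bad[1]))
    weighted_graph(A)
  }
}

guess_format <- function(path, format) {
  if (!is.null(format))
    return(match.arg(format, c("edge_tsv", "adjacency_csv")))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "edge_tsv",
         csv = "adjacency_csv",
         stop("cannot guess format from extension '.", ext,
              "'; pass format = 'edge_tsv' or 'adjacency_csv'"))
}

#' Write a weighted graph to disk
#'
#' Inverse of [read_graph()]. Edge lists are written in canonical form
#' (`u < v`, sorted by `u` then `v`) with 17 significant digits so that a
#' write-then-read round trip reproduces the adjacency matrix exactly.
#'
#' @param g a [weighted_graph()].
#' @inheritParams read_graph
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = NULL) {
  format <- guess_format(path, format)
  if (format == "edge_tsv") {
    idx <- which(upper.tri(g$A) & g$A > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    lines <- sprintf("%d\t%d\t%.17g",
                     idx[, 1] - 1L, idx[, 2] - 1L, g$A[idx])
    writeLines(lines, path)
  } else {
    writeLines(apply(g$A, 1, function(row)
      paste(sprintf("%.17g", row), collapse = ",")), path)
  }
  invisible(path)
}

config_schema <- list(
  n        = list(default = 100,      check = function(x) x >= 2 && x == round(x)),
  family   = list(default = "normal", check = function(x) x %in% c("normal", "lognormal")),
  mu       = list(default = NULL,     check = function(x) is.numeric(x) && is.finite(x)),
  sigma    = list(default = NULL,     check = function(x) is.numeric(x) && x > 0),
  tau      = list(default = 3,        check = function(x) is.numeric(x) && x > 0),
  p_random = list(default = 0.2,      check = function(x) is.numeric(x) && x >= 0 && x <= 1),
  r        = list(default = 4000,     check = function(x) x >= 0 && x == round(x)),
  seed     = list(default = 1,        check = function(x) x == round(x)),
  snapshot_every = list(default = 0,  check = function(x) x >= 0 && x == round(x)),
  reps     = list(default = 15,       check = function(x) x >= 1 && x == round(x)),
  tier     = list(default = "desk",   check = function(x) x %in% c("smoke", "desk", "full"))
)

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, fills in defaults (`n = 100`,
#' `p_random = 0.2`, `r = 4000`, normal weights), rejects unknown keys and
#' reports range violations field by field. `mu`/`sigma` default to the
#' family's standard parameters when absent.
#'
#' @param path JSON file; an empty object `{}` yields all defaults.
#' @return Named list of validated parameters.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- lapply(names(config_schema), function(key) {
    val <- if (key %in% names(cfg)) cfg[[key]] else config_schema[[key]]$default
    if (!is.null(val) && !isTRUE(config_schema[[key]]$check(val)))
      stop(sprintf("config field '%s': invalid value %s",
                   key, deparse(val)))
    val
  })
  names(out) <- names(config_schema)
  if (is.null(out$mu)) out$mu <- if (out$family == "normal") 1 else 0
  if (is.null(out$sigma)) out$sigma <- if (out$family == "normal") 0.25 else 1
  out
}

#' Write a run manifest
#'
#' Records everything needed to re-run an invocation bit-identically:
#' timestamp, package version, the full parameter set, and input/output
#' paths, as pretty-printed JSON next to the outputs.
#'
#' @param path manifest file to write (JSON).
#' @param params named list of run parameters (including seeds).
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, inputs = character(),
                           outputs = character()) {
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tool = "heatrewire",
    version = as.character(packageVersion("heatrewire")),
    parameters = params,
    inputs = inputs,
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
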