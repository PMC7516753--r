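#' Read a delimited numeric data matrix
#'
#' Parses a delimited text file into a numeric matrix, auto-detecting an
#' optional header line, and optionally splitting off a point-weight column.
#' Non-numeric or missing cells are rejected with the offending row and
#' column named.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param weight_column name or index of a weight column to extract, or
#'   `NULL`.
#' @return list with `X` (numeric matrix) and `weights` (numeric vector or
#'   `NULL`).
#' @export
read_matrix <- function(path, delimiter = "\t", weight_column = NULL) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  fields <- strsplit(first, delimiter, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path, sep = delimiter, header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  M <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
           dimnames = list(NULL, colnames(df))))
  bad <- which(is.na(M) | is.nan(M), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cn <- colnames(M)[bad[1L, 2L]] %||% as.character(bad[1L, 2L])
    stop(sprintf("non-numeric or missing value at row %d, column %s",
                 bad[1L, 1L], cn))
  }
  weights <- NULL
  if (!is.null(weight_column)) {
    wi <- if (is.character(weight_column))
      match(weight_column, colnames(M)) else as.integer(weight_column)
    if (is.na(wi) || wi < 1L || wi > ncol(M))
      stop("weight column not found: ", weight_column)
    weights <- M[, wi]
    M <- M[, -wi, drop = FALSE]
  }
  list(X = M, weights = weights)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a fitted principal graph to a directory
#'
#' Serializes a result as three plain-text files: `nodes.tsv` (node_id and
#' coordinates), `edges.tsv` (source, target, lambda), and `meta.json`
#' (alpha, per-node mu, trimming radius, mode, history and provenance).
#' [read_graph()] restores the result; positions and moduli round-trip at
#' full double precision.
#'
#' @param result a `principal_graph` (or list with `graph` and `positions`).
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_graph <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pos <- as.matrix(result$positions)
  graph <- result$graph
  nodes <- data.frame(node_id = seq_len(nrow(pos)))
  for (j in seq_len(ncol(pos)))
    nodes[[paste0("x_", j)]] <- fmt_num(pos[, j])
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  edges <- data.frame(source = graph$edges[, 1L], target = graph$edges[, 2L],
                      lambda = fmt_num(graph$lambdas))
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(alpha = graph$alpha, mu = as.numeric(graph$mus),
               trimming_radius = result$trimming_radius %||% Inf,
               mode = result$config$mode %||% NA,
               seed = result$config$seed %||% NA,
               n_nodes = graph$n_nodes,
               energy = if (!is.null(result$energy))
                 list(U_total = result$energy$U_total,
                      approximation_term = result$energy$approximation_term,
                      U_E = result$energy$U_E, U_R = result$energy$U_R)
               else NULL,
               history = result$history)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(dir)
}

#' Read a principal graph written by [write_graph()]
#'
#' @param dir directory containing `nodes.tsv`, `edges.tsv`, `meta.json`.
#' @return a `principal_graph` (without data-dependent fields).
#' @export
read_graph <- function(dir) {
  nf <- file.path(dir, "nodes.tsv")
  ef <- file.path(dir, "edges.tsv")
  mf <- file.path(dir, "meta.json")
  for (f in c(nf, ef, mf))
    if (!file.exists(f)) stop("missing graph file: ", f)
  nodes <- utils::read.table(nf, sep = "\t", header = TRUE)
  edges <- utils::read.table(ef, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  pos <- as.matrix(nodes[, -1L, drop = FALSE])
  dimnames(pos) <- NULL
  tr <- meta$trimming_radius
  if (is.null(tr) || is.character(tr)) tr <- Inf
  em <- if (nrow(edges) > 0L) cbind(edges$source, edges$target) else NULL
  graph <- elastic_graph(em, n_nodes = meta$n_nodes,
                         lambda = if (nrow(edges) > 0L) edges$lambda else 0.01,
                         mu = as.numeric(meta$mu), alpha = meta$alpha)
  structure(list(graph = graph, positions = pos, energy = NULL,
                 partition = NULL,
                 history = as.data.frame(meta$history),
                 config = list(mode = meta$mode, seed = meta$seed),
                 trimming_radius = tr),
            class = "principal_graph")
}
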