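# Network serialization: versioned JSON schema and Graphviz DOT export.

NET_SCHEMA <- "mitebn-net/1"

#' Write a network (or bare DAG) as JSON
#'
#' Schema `mitebn-net/1`: `nodes` (canonical order), `edges` (objects with
#' `from`/`to`, canonical order) and, for a fitted network, `cpts` mapping
#' each node to its parent list and `P(node = 1 | cfg)` vector. Probabilities
#' are written at full precision; output is byte-deterministic for a given
#' object.
#'
#' @param net a `bn_fit` or `bn_dag`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_net_json <- function(net, path) {
  dag <- if (inherits(net, "bn_fit")) net$dag else net
  if (!inherits(dag, "bn_dag")) stop("'net' must be a bn_fit or bn_dag")
  e <- dag_edges(dag)
  doc <- list(
    schema = NET_SCHEMA,
    nodes = as.list(dag$nodes),
    edges = lapply(seq_len(nrow(e)),
                   function(i) list(from = e[i, 1], to = e[i, 2]))
  )
  if (inherits(net, "bn_fit")) {
    doc$cpts <- lapply(net$cpts, function(cpt) {
      list(parents = as.list(cpt$parents), p1 = cpt$p1)
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a network from JSON
#'
#' Inverse of [write_net_json()]. A document without `cpts` yields a
#' `bn_dag`, otherwise a `bn_fit`.
#'
#' @param path path to a `mitebn-net/1` JSON file.
#' @return a `bn_fit` or `bn_dag`.
#' @export
read_net_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!identical(doc$schema, NET_SCHEMA)) {
    stop("unsupported network schema: ", doc$schema %||% "<missing>")
  }
  edges <- if (length(doc$edges)) {
    as.matrix(as.data.frame(doc$edges)[, c("from", "to")])
  } else {
    NULL
  }
  dag <- bn_dag(doc$nodes, edges)
  if (is.null(doc$cpts)) {
    return(dag)
  }
  cpts <- lapply(doc$cpts, function(spec) {
    list(parents = unlist(spec$parents) %||% character(0), p1 = spec$p1)
  })
  bn_custom(dag, cpts)
}

#' Export a DAG in Graphviz DOT format
#'
#' One node statement per component and one directed edge statement per DAG
#' edge, both in canonical order, so re-exporting the same graph is
#' byte-identical.
#'
#' @param net a `bn_fit` or `bn_dag`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_dag_dot <- function(net, path) {
  dag <- if (inherits(net, "bn_fit")) net$dag else net
  if (!inherits(dag, "bn_dag")) stop("'net' must be a bn_fit or bn_dag")
  e <- dag_edges(dag)
  lines <- c(
    "digraph bn {",
    sprintf("  \"%s\";", dag$nodes),
    if (nrow(e)) sprintf("  \"%s\" -> \"%s\";", e[, 1], e[, 2]),
    "}"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
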