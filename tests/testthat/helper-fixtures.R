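# Shared builders for test fixtures: small panels, random DAGs/networks and
# the published per-component counts used as arithmetic oracles.

# A minimal well-formed panel data frame; every sIgE defaults to `sige`.
tiny_panel_df <- function(ids, ages, sige = 0.1, tige = 100) {
  df <- data.frame(id = as.character(ids), age = ages,
                   tIgE = rep_len(tige, length(ids)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (k in hdm_components()) df[[k]] <- rep_len(sige, length(ids))
  df
}

write_csv_lines <- function(df, path) {
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) apply(df, 1, function(r) paste(trimws(r), collapse = ",")))
  writeLines(lines, path)
  path
}

# Random DAG: random topological order, each forward pair an edge w.p. p_edge.
rand_dag <- function(nodes, p_edge = 0.3) {
  ord <- sample(nodes)
  dag <- bn_dag(nodes)
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (i < j && runif(1) < p_edge) dag <- add_edge(dag, ord[i], ord[j])
    }
  }
  dag
}

# Random strictly-positive CPTs on a DAG.
rand_net <- function(dag, lo = 0.02, hi = 0.98) {
  cpts <- lapply(dag$nodes, function(v) {
    k <- length(parents_of(dag, v))
    list(p1 = runif(2^k, lo, hi))
  })
  names(cpts) <- dag$nodes
  bn_custom(dag, cpts)
}

# Published per-component sensitized counts and the shares printed alongside
# them (denominator: the 5,170 patients sensitized to >= 1 component), in
# catalog order, for the whole sample / children / adults.
table1_counts <- function() {
  data.frame(
    component = hdm_components(),
    n_all    = c(2821, 3743, 2720, 3701, 1512, 1172, 320, 30, 438, 1422, 2843),
    share_all = c(54.56, 72.40, 52.61, 71.59, 29.25, 22.67, 6.19, 0.58, 8.47,
                  27.50, 54.99),
    n_children = c(2083, 2568, 1981, 2548, 1065, 834, 207, 14, 234, 952, 2011),
    share_children = c(40.29, 49.67, 38.32, 49.28, 20.60, 16.13, 4.00, 0.27,
                       4.53, 18.41, 38.90),
    n_adults = c(738, 1175, 741, 1153, 447, 338, 114, 16, 204, 470, 832),
    share_adults = c(14.27, 22.73, 14.33, 22.30, 8.65, 6.54, 2.21, 0.31, 3.95,
                     9.09, 16.09),
    stringsAsFactors = FALSE
  )
}

skeleton_of <- function(dag) {
  e <- dag_edges(dag)
  if (!nrow(e)) return(character(0))
  sort(apply(e, 1, function(r) paste(sort(r), collapse = " ~ ")))
}
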