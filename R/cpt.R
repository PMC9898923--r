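# Conditional probability tables and the fitted-network container.
#
# A CPT for a binary node stores P(node = 1 | parent configuration) as a
# vector of length 2^|parents|; parents are kept in canonical node order and
# configuration cfg maps to index 1 + sum(parent_value_i * 2^(i-1)).

new_cpt <- function(node, parents, p1, counts = NULL) {
  nb <- 2L^length(parents)
  if (length(p1) != nb) {
    stop("CPT for '", node, "' needs ", nb, " entries, got ", length(p1))
  }
  ok <- is.na(p1) | (p1 >= 0 & p1 <= 1)
  if (!all(ok)) stop("CPT probabilities for '", node, "' outside [0, 1]")
  structure(list(node = node, parents = parents, p1 = as.numeric(p1),
                 counts = counts),
            class = "bn_cpt")
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat("<bn_cpt> P(", x$node, " = 1 | ",
      if (length(x$parents)) paste(x$parents, collapse = ", ") else "-",
      ")\n", sep = "")
  cfg <- bitgrid(length(x$parents))
  lab <- if (ncol(cfg)) {
    apply(cfg, 1, function(b) paste(x$parents, "=", b, collapse = ", "))
  } else {
    "(no parents)"
  }
  for (i in seq_along(x$p1)) {
    cat(sprintf("  %s : %.4f\n", lab[i], x$p1[i]))
  }
  invisible(x)
}

#' Assemble a Bayesian network from a DAG and CPTs
#'
#' @param dag a `bn_dag`.
#' @param cpts named list, one entry per node, each a list with `parents`
#'   (may be omitted; taken from the DAG) and `p1`, the vector of
#'   `P(node = 1 | parent configuration)` with parents in canonical node
#'   order and configuration index `1 + sum(value_i * 2^(i-1))`.
#' @return a `bn_fit`.
#' @export
bn_custom <- function(dag, cpts) {
  built <- lapply(dag$nodes, function(v) {
    spec <- cpts[[v]]
    if (is.null(spec)) stop("no CPT supplied for node ", v)
    if (inherits(spec, "bn_cpt")) spec <- list(parents = spec$parents, p1 = spec$p1)
    pa <- sort_canonical(parents_of(dag, v), dag$nodes)
    if (!is.null(spec$parents) && !identical(sort_canonical(spec$parents, dag$nodes), pa)) {
      stop("CPT parents for '", v, "' disagree with the DAG")
    }
    new_cpt(v, pa, spec$p1)
  })
  names(built) <- dag$nodes
  new_bn_fit(dag, built)
}

new_bn_fit <- function(dag, cpts) {
  stopifnot(inherits(dag, "bn_dag"), identical(names(cpts), dag$nodes))
  for (v in dag$nodes) {
    pa <- sort_canonical(parents_of(dag, v), dag$nodes)
    if (!identical(cpts[[v]]$parents, pa)) {
      stop("CPT parents for '", v, "' inconsistent with DAG")
    }
  }
  structure(list(dag = dag, cpts = cpts), class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("<bn_fit> ", length(x$dag$nodes), " node(s), ",
      nrow(dag_edges(x$dag)), " edge(s), ",
      sum(vapply(x$cpts, function(c) length(c$p1), 0L)),
      " CPT entrie(s)\n", sep = "")
  invisible(x)
}

#' Fit CPTs by (smoothed) maximum likelihood
#'
#' For every node and parent configuration,
#' `P(node = 1 | cfg) = (n1 + alpha) / (n + 2 * alpha)` where `n1` and `n`
#' are the configuration's positive and total counts. The default
#' `alpha = 1` (symmetric Laplace prior) keeps every entry defined even for
#' parent configurations unobserved in the data; with `alpha = 0` (plain
#' maximum likelihood) an unobserved configuration yields `NA`, never `0/0`.
#'
#' @param dag a `bn_dag` whose nodes are columns of `data`.
#' @param data a `sens_matrix` or binary matrix with named columns.
#' @param alpha pseudocount, `>= 0` (default 1).
#' @return a `bn_fit`.
#' @export
fit_cpds <- function(dag, data, alpha = 1) {
  d <- as_binary_matrix(data)
  if (!all(dag$nodes %in% colnames(d))) {
    stop("every DAG node must be a data column")
  }
  if (alpha < 0) stop("'alpha' must be >= 0")
  cpts <- lapply(dag$nodes, function(v) {
    pa <- sort_canonical(parents_of(dag, v), dag$nodes)
    k <- length(pa)
    nb <- 2L^k
    cfg <- if (k) {
      as.integer(d[, pa, drop = FALSE] %*% 2^(seq_len(k) - 1)) + 1L
    } else {
      rep(1L, nrow(d))
    }
    n1 <- tabulate(cfg[d[, v] == 1L], nbins = nb)
    nc <- tabulate(cfg, nbins = nb)
    p1 <- (n1 + alpha) / (nc + 2 * alpha)
    if (alpha == 0) p1[nc == 0] <- NA_real_
    new_cpt(v, pa, p1, counts = nc)
  })
  names(cpts) <- dag$nodes
  new_bn_fit(dag, cpts)
}

# CPT entry P(node = val | parent values), vectorized over rows of `pavals`
# (a matrix with one column per parent, canonical order).
cpt_prob <- function(cpt, val, pavals) {
  k <- length(cpt$parents)
  idx <- if (k) {
    as.integer(pavals %*% 2^(seq_len(k) - 1)) + 1L
  } else {
    rep(1L, length(val))
  }
  p1 <- cpt$p1[idx]
  ifelse(val == 1L, p1, 1 - p1)
}
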