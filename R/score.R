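# Network scoring: multinomial log-likelihood and BIC, decomposable per
# family (node + parents), which is what makes greedy search cheap.

# Maximized log-likelihood of one family: sum over parent configurations of
# n1*log(n1/nc) + n0*log(n0/nc), with the 0*log(0) = 0 convention.
family_loglik <- function(x, pamat) {
  n <- length(x)
  k <- ncol(pamat)
  nb <- 2L^k
  cfg <- if (k) {
    as.integer(pamat %*% 2^(seq_len(k) - 1)) + 1L
  } else {
    rep(1L, n)
  }
  n1 <- tabulate(cfg[x == 1L], nbins = nb)
  nc <- tabulate(cfg, nbins = nb)
  n0 <- nc - n1
  denom <- pmax(nc, 1L)
  sum(xlogy(n1, n1 / denom) + xlogy(n0, n0 / denom))
}

#' Maximized log-likelihood of a DAG
#'
#' Sum over nodes of the maximized multinomial log-likelihood of each node
#' given its parents. Adding an edge can never decrease this quantity (the
#' models are nested), which is why a complexity penalty is needed for
#' structure search.
#'
#' @param dag a `bn_dag` whose nodes are all columns of `data`.
#' @param data a `sens_matrix` or binary matrix with named columns.
#' @return log-likelihood (natural log).
#' @export
bn_loglik <- function(dag, data) {
  d <- as_binary_matrix(data)
  if (!all(dag$nodes %in% colnames(d))) {
    stop("every DAG node must be a data column")
  }
  ll <- 0
  for (v in dag$nodes) {
    pa <- parents_of(dag, v)
    ll <- ll + family_loglik(d[, v], d[, pa, drop = FALSE])
  }
  ll
}

#' BIC network score
#'
#' `bn_loglik(dag, data) - log(n)/2 * k`, where `k` is the number of free
#' parameters: one per parent configuration per binary node, i.e.
#' `2^|parents|` for each node. Higher is better. The score is decomposable:
#' only the families touched by a candidate move need rescoring.
#'
#' @inheritParams bn_loglik
#' @return BIC score (higher is better).
#' @export
bic_score <- function(dag, data) {
  d <- as_binary_matrix(data)
  if (!all(dag$nodes %in% colnames(d))) {
    stop("every DAG node must be a data column")
  }
  n <- nrow(d)
  if (n < 1) stop("need at least one observation")
  total <- 0
  for (v in dag$nodes) {
    pa <- parents_of(dag, v)
    total <- total + family_loglik(d[, v], d[, pa, drop = FALSE]) -
      log(n) / 2 * 2^length(pa)
  }
  total
}
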