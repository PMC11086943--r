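#' Count co-occurrences (V-motifs) on one layer of a bipartite graph
#'
#' For every unordered pair of nodes on the chosen layer, counts the number
#' of common neighbors on the opposite layer,
#' \eqn{V^*_{ij} = \sum_\alpha b_{i\alpha} b_{j\alpha}}.
#'
#' @param g a [bipartite_graph()].
#' @param layer `"top"` or `"bottom"`: the layer to project on.
#' @return An object of class `cooccurrence_table`: data frame with columns
#'   `i`, `j` (node ids, i < j in layer order) and `v` (observed count),
#'   one row per unordered pair, plus attributes `layer` and `nodes`.
#' @export
count_vmotifs <- function(g, layer = c("top", "bottom")) {
  stopifnot(inherits(g, "bipartite_graph"))
  layer <- match.arg(layer)
  B <- if (layer == "top") g$biadjacency else t(g$biadjacency)
  nodes <- rownames(B)
  n <- nrow(B)
  if (n < 2) stop("layer must have at least 2 nodes to project")
  V <- tcrossprod(B)
  idx <- which(upper.tri(V), arr.ind = TRUE)
  out <- data.frame(
    i = nodes[idx[, 1]],
    j = nodes[idx[, 2]],
    v = V[idx],
    stringsAsFactors = FALSE
  )
  structure(out, layer = layer, nodes = nodes, class = c("cooccurrence_table", "data.frame"))
}

#' Poisson-binomial upper-tail p-value
#'
#' Survival function \eqn{P(V \ge v)} of a sum of independent Bernoulli
#' variables with heterogeneous success probabilities, the null distribution
#' of a co-occurrence count under the BiCM (pair \eqn{(i,j)} has success
#' probabilities \eqn{p_{i\alpha} p_{j\alpha}} over the opposite layer).
#' Computed by exact dynamic-programming convolution in
#' \eqn{O(\mathrm{len} \cdot v)}; a normal approximation (with continuity
#' correction) is only used above `approx_threshold` trials and is flagged
#' via the `"approx"` attribute.
#'
#' @param probs vector of success probabilities, each in \[0, 1\].
#' @param observed non-negative integer count.
#' @param approx_threshold number of trials above which the normal
#'   approximation is used; default `Inf` (always exact).
#' @return p-value in (0, 1\]; exactly 0 only when `observed` exceeds the
#'   number of trials that can succeed.
#' @examples
#' poisson_binomial_sf(c(0.5, 0.5), 2) # 0.25
#' @export
poisson_binomial_sf <- function(probs, observed, approx_threshold = Inf) {
  if (length(observed) != 1 || is.na(observed) || observed < 0 ||
      observed != floor(observed)) {
    stop("observed must be a single non-negative integer")
  }
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (observed == 0) return(1)
  if (observed > length(probs)) return(0)

  n_one <- sum(probs == 1)
  probs <- probs[probs > 0 & probs < 1]
  v <- observed - n_one
  if (v <= 0) return(1)
  if (v > length(probs)) return(0)

  if (length(probs) > approx_threshold) {
    mu <- sum(probs)
    sigma <- sqrt(sum(probs * (1 - probs)))
    p <- stats::pnorm(v - 0.5, mean = mu, sd = sigma, lower.tail = FALSE)
    return(structure(min(max(p, 0), 1), approx = TRUE))
  }

  # dp[m+1] = P(exactly m successes among trials seen so far), m = 0..v-1
  dp <- c(1, rep(0, v - 1))
  for (p in probs) {
    dp <- dp * (1 - p) + c(0, dp[-v]) * p
  }
  min(max(1 - sum(dp), 0), 1)
}

#' Benjamini-Hochberg selection over a family of p-values
#'
#' Sorts the m p-values, finds \eqn{\hat k = \max\{k : p_{(k)} \le k\alpha/m\}}
#' and rejects every hypothesis with \eqn{p \le p_{(\hat k)}}.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param alpha target false discovery rate, in (0, 1).
#' @return list with `reject` (logical, in input order), `threshold` (the
#'   largest accepted p-value, 0 when nothing is rejected), `k` (number of
#'   rejections along the sorted sequence) and `m`.
#' @export
bh_select <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) stop("pvalues must be nonempty")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("pvalues must lie in [0, 1]")
  }
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  m <- length(pvalues)
  ps <- sort(pvalues)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (length(ok) == 0) {
    return(list(reject = rep(FALSE, m), threshold = 0, k = 0L, m = m))
  }
  k <- max(ok)
  thr <- ps[k]
  list(reject = pvalues <= thr, threshold = thr, k = k, m = m)
}

#' Statistically validated monopartite projection of a bipartite graph
#'
#' For every unordered pair on the chosen layer, compares the observed
#' co-occurrence with its Poisson-binomial null distribution under the
#' fitted BiCM (success probabilities \eqn{p_{i\alpha} p_{j\alpha}}), then
#' controls the false discovery rate over all \eqn{\binom{N}{2}} pairs with
#' Benjamini-Hochberg. Pairs surviving the filter become edges of the
#' validated monopartite projection; nodes with at least one validated edge
#' are the *validated nodes*.
#'
#' @param g a [bipartite_graph()].
#' @param model a [fit_bicm()] fit of `g`.
#' @param layer `"top"` or `"bottom"`.
#' @param alpha false discovery rate (default 0.05).
#' @param approx_threshold passed to [poisson_binomial_sf()].
#' @return An object of class `validated_projection`: list with `layer`,
#'   `alpha`, `m`, `threshold`, `table` (the co-occurrence table with a
#'   `pvalue` and `validated` column), `graph` (igraph over all layer nodes
#'   with the validated edges) and `validated_nodes`.
#' @export
validate_projection <- function(g, model, layer = c("top", "bottom"),
                                alpha = 0.05, approx_threshold = Inf) {
  layer <- match.arg(layer)
  stopifnot(inherits(g, "bipartite_graph"), inherits(model, "bicm"))
  if (!all(dim(model$p) == dim(g$biadjacency))) {
    stop("model was not fitted on a graph of this shape")
  }
  tab <- count_vmotifs(g, layer)
  P <- if (layer == "top") model$p else t(model$p)
  nodes <- attr(tab, "nodes")
  ii <- match(tab$i, nodes)
  jj <- match(tab$j, nodes)
  pv <- rep(1, nrow(tab))
  nz <- which(tab$v > 0)
  for (r in nz) {
    pv[r] <- poisson_binomial_sf(P[ii[r], ] * P[jj[r], ], tab$v[r],
                                 approx_threshold = approx_threshold)
  }
  tab$pvalue <- pv
  sel <- bh_select(pv, alpha)
  tab$validated <- sel$reject

  gr <- igraph::graph_from_data_frame(
    tab[tab$validated, c("i", "j"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  structure(
    list(
      layer = layer, alpha = alpha, m = sel$m, threshold = sel$threshold,
      table = tab, graph = gr,
      validated_nodes = sort(nodes[unique(c(ii[sel$reject], jj[sel$reject]))])
    ),
    class = "validated_projection"
  )
}

#' @export
print.validated_projection <- function(x, ...) {
  cat(sprintf(
    "validated_projection (%s layer): %d/%d pairs validated (alpha %.3g, p-hat %.3g), %d validated nodes\n",
    x$layer, sum(x$table$validated), x$m, x$alpha, x$threshold,
    length(x$validated_nodes)
  ))
  invisible(x)
}
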