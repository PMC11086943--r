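#' Fit the Bipartite Configuration Model (BiCM)
#'
#' Maximum-entropy null model for binary bipartite networks with both degree
#' sequences as constraints. Maximizing the Shannon entropy of the graph
#' ensemble subject to the expected degrees matching the observed ones yields
#' a graph probability that factorizes over node pairs into independent
#' Bernoulli links with
#' \deqn{p_{i\alpha} = \frac{e^{-(\theta_i + \eta_\alpha)}}{1 + e^{-(\theta_i + \eta_\alpha)}},}
#' where \eqn{\theta_i} and \eqn{\eta_\alpha} are the Lagrange multipliers of
#' the top- and bottom-layer degree constraints. The multipliers are fixed by
#' likelihood maximization, which is equivalent to solving
#' \eqn{\sum_\alpha p_{i\alpha} = k_i^*} and
#' \eqn{\sum_i p_{i\alpha} = h_\alpha^*} (the observed degrees).
#'
#' The solver works on the degree-reduced system (nodes sharing a degree share
#' a multiplier) with a damped fixed-point iteration on the likelihood
#' conditions; if that stalls, it falls back to quasi-Newton maximization of
#' the reduced log-likelihood. Degree-0 and full-degree rows/columns are
#' peeled off before solving and reinstated with probabilities exactly 0 or 1,
#' the limit of the model, so no multiplier diverges.
#'
#' @param g a [bipartite_graph()].
#' @param tol convergence tolerance on the maximum absolute degree residual
#'   \eqn{\max(|\langle k_i\rangle - k_i^*|, |\langle h_\alpha\rangle - h_\alpha^*|)}.
#' @param max_iter maximum fixed-point iterations.
#' @return An object of class `bicm`: list with `theta`, `eta` (named
#'   multiplier vectors; `Inf`/`-Inf` for peeled degree-0/full nodes), `p`
#'   (link-probability matrix), `residual`, `iterations`, `converged`.
#' @examples
#' g <- bipartite_graph(matrix(c(1, 0, 0, 1), 2, 2))
#' m <- fit_bicm(g)
#' m$p  # all entries 1/2
#' @export
fit_bicm <- function(g, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(g, "bipartite_graph"), tol > 0, max_iter >= 1)
  n_top <- length(g$top_nodes)
  n_bot <- length(g$bottom_nodes)
  if (n_top == 0 || n_bot == 0) stop("bipartite graph has an empty layer")

  k <- g$k
  h <- g$h

  # Peel degenerate nodes, writing their probabilities as they go: a node of
  # residual degree 0 links to the still-active opposite nodes with p = 0; a
  # node whose residual degree equals the number of active opposite nodes
  # links to all of them with p = 1 (the opposite residual degrees shrink by
  # one per certain link). Repeat to a fixed point; order matters, so the
  # probabilities towards already-peeled nodes were fixed when those left.
  p <- matrix(NA_real_, n_top, n_bot, dimnames = dimnames(g$biadjacency))
  theta <- rep(NA_real_, n_top)
  eta <- rep(NA_real_, n_bot)
  active_r <- rep(TRUE, n_top)
  active_c <- rep(TRUE, n_bot)
  k_red <- k
  h_red <- h
  repeat {
    changed <- FALSE
    z <- active_r & k_red == 0
    if (any(z)) {
      p[z, active_c] <- 0; theta[z] <- Inf; active_r[z] <- FALSE
      changed <- TRUE
    }
    z <- active_c & h_red == 0
    if (any(z)) {
      p[active_r, z] <- 0; eta[z] <- Inf; active_c[z] <- FALSE
      changed <- TRUE
    }
    f <- active_r & k_red == sum(active_c) & sum(active_c) > 0
    if (any(f)) {
      p[f, active_c] <- 1; theta[f] <- -Inf
      h_red[active_c] <- h_red[active_c] - sum(f)
      active_r[f] <- FALSE
      changed <- TRUE
    }
    f <- active_c & h_red == sum(active_r) & sum(active_r) > 0
    if (any(f)) {
      p[active_r, f] <- 1; eta[f] <- -Inf
      k_red[active_r] <- k_red[active_r] - sum(f)
      active_c[f] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }

  core_r <- which(active_r)
  core_c <- which(active_c)
  iterations <- 0L
  residual <- 0

  if (length(core_r) > 0 && length(core_c) > 0) {
    fit <- bicm_solve_core(k_red[core_r], h_red[core_c], tol, max_iter)
    iterations <- fit$iterations
    residual <- fit$residual
    if (!fit$converged) {
      stop(sprintf(
        "BiCM solver did not converge: residual %.3e after %d iterations (tol %.1e)",
        fit$residual, fit$iterations, tol
      ))
    }
    theta[core_r] <- fit$theta
    eta[core_c] <- fit$eta
    p[core_r, core_c] <- plogis_pair(fit$theta, fit$eta)
  }

  names(theta) <- g$top_nodes
  names(eta) <- g$bottom_nodes
  structure(
    list(
      theta = theta, eta = eta, p = p,
      residual = residual, iterations = iterations, converged = TRUE
    ),
    class = "bicm"
  )
}

# p_{i alpha} = 1 / (1 + exp(theta_i + eta_alpha)), computed as a stable
# logistic over the outer sum.
plogis_pair <- function(theta, eta) {
  s <- outer(theta, eta, "+")
  stats::plogis(-s)
}

# Degree-reduced solver on strictly positive, non-full degree sequences.
# Works with x_r = exp(-theta_r), y_s = exp(-eta_s) over unique degrees.
bicm_solve_core <- function(k, h, tol, max_iter) {
  uk <- sort(unique(k))
  uh <- sort(unique(h))
  ck <- as.numeric(table(factor(k, levels = uk)))
  ch <- as.numeric(table(factor(h, levels = uh)))
  L <- sum(k)

  x <- uk / sqrt(L)
  y <- uh / sqrt(L)

  resid_fun <- function(x, y) {
    xy <- outer(x, y)
    P <- xy / (1 + xy)
    rk <- drop(P %*% ch) - uk
    rh <- drop(crossprod(P, ck)) - uh
    max(abs(rk), abs(rh))
  }

  residual <- resid_fun(x, y)
  it <- 0L
  while (residual > tol && it < max_iter) {
    it <- it + 1L
    # x update: x_r = uk_r / sum_s ch_s y_s / (1 + x_r y_s)
    denom <- (1 / (1 + outer(x, y))) %*% (ch * y)
    x <- uk / drop(denom)
    denom <- crossprod(1 / (1 + outer(x, y)), ck * x)
    y <- uh / drop(denom)
    residual <- resid_fun(x, y)
  }

  if (residual > tol) {
    # quasi-Newton fallback on the reduced log-likelihood in log coordinates
    obj <- function(par) {
      lx <- par[seq_along(uk)]
      ly <- par[length(uk) + seq_along(uh)]
      s <- outer(lx, ly, "+") # log(x_r y_s)
      # -loglik (up to constants): sum_rs ck ch log(1+e^s) - sum_r ck uk lx - ...
      sum(outer(ck, ch) * log1p(exp(pmin(s, 700)))) -
        sum(ck * uk * lx) - sum(ch * uh * ly)
    }
    grad <- function(par) {
      lx <- par[seq_along(uk)]
      ly <- par[length(uk) + seq_along(uh)]
      xy <- exp(outer(lx, ly, "+"))
      P <- xy / (1 + xy)
      c(ck * (drop(P %*% ch) - uk), ch * (drop(crossprod(P, ck)) - uh))
    }
    res <- stats::optim(c(log(x), log(y)), obj, grad, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-15))
    x <- exp(res$par[seq_along(uk)])
    y <- exp(res$par[length(uk) + seq_along(uh)])
    residual <- resid_fun(x, y)
  }

  theta_u <- -log(x)
  eta_u <- -log(y)
  list(
    theta = theta_u[match(k, uk)],
    eta = eta_u[match(h, uh)],
    residual = residual,
    iterations = it,
    converged = residual <= tol
  )
}

#' Log-likelihood of a bipartite graph under a BiCM
#'
#' Returns \eqn{\sum_{i\alpha} [b_{i\alpha}\ln p_{i\alpha} +
#' (1-b_{i\alpha})\ln(1-p_{i\alpha})]} with the convention
#' \eqn{0\cdot\ln 0 = 0}.
#'
#' @param model a fitted [fit_bicm()] object (or any list with a `p` matrix).
#' @param g a [bipartite_graph()] of matching dimensions.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, g) {
  stopifnot(inherits(g, "bipartite_graph"))
  p <- model$p
  B <- g$biadjacency
  if (!all(dim(p) == dim(B))) stop("model and graph have incompatible shapes")
  t1 <- ifelse(B == 1, log(p), 0)
  t0 <- ifelse(B == 0, log1p(-p), 0)
  # 0 * log(0) := 0 also when p hits exactly 0/1 on the matching entry
  t1[B == 1 & p == 1] <- 0
  t0[B == 0 & p == 0] <- 0
  sum(t1) + sum(t0)
}

#' Probability of a specific bipartite graph under a BiCM
#'
#' The ensemble probability \eqn{P(G) = \prod_{i\alpha}
#' p_{i\alpha}^{b_{i\alpha}} (1-p_{i\alpha})^{1-b_{i\alpha}}}.
#'
#' @inheritParams log_likelihood
#' @return scalar probability.
#' @export
graph_probability <- function(model, g) {
  exp(log_likelihood(model, g))
}

#' Sample a bipartite graph from a fitted BiCM
#'
#' Each biadjacency entry is drawn independently Bernoulli(\eqn{p_{i\alpha}}).
#'
#' @param model a fitted [fit_bicm()] object.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return A [bipartite_graph()] with the model's node ids.
#' @export
sample_graph <- function(model, seed = NULL) {
  p <- model$p
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(as.numeric(stats::runif(length(p)) < p), nrow(p), ncol(p),
              dimnames = dimnames(p))
  bipartite_graph(B)
}

#' @export
print.bicm <- function(x, ...) {
  cat(sprintf(
    "BiCM: %d x %d, residual %.2e after %d iterations\n",
    nrow(x$p), ncol(x$p), x$residual, x$iterations
  ))
  invisible(x)
}

#' Serialize a fitted BiCM to JSON
#'
#' Dumps multipliers and convergence metadata (not the dense probability
#' matrix, which is recomputable from the multipliers).
#'
#' @param model a fitted [fit_bicm()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bicm_json <- function(model, path) {
  jsonlite::write_json(
    list(
      theta = as.list(model$theta), eta = as.list(model$eta),
      residual = model$residual, iterations = model$iterations
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
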