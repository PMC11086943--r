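# Shared fixture builders; everything is generated in code under fixed seeds.

# random binary bipartite graph
random_bipartite <- function(n_top, n_bot, rate, seed) {
  set.seed(seed)
  B <- matrix(as.numeric(stats::runif(n_top * n_bot) < rate), n_top, n_bot)
  bipartite_graph(B)
}

# tiny post table builder
make_posts <- function(...) {
  rows <- list(...)
  df <- data.frame(
    post_id = vapply(rows, `[[`, "", "id"),
    author_id = vapply(rows, `[[`, "", "author"),
    author_verified = vapply(rows, function(r) isTRUE(r$verified), TRUE),
    retweeted_author_id = vapply(rows, function(r) {
      if (is.null(r$rt)) NA_character_ else r$rt
    }, ""),
    timestamp = NA_character_,
    stringsAsFactors = FALSE
  )
  df$urls <- lapply(rows, function(r) if (is.null(r$urls)) character(0) else r$urls)
  echo_dataset(df[c("post_id", "author_id", "author_verified",
                    "retweeted_author_id", "urls", "timestamp")])
}

p_row <- function(id, author, verified = FALSE, rt = NULL, urls = NULL) {
  list(id = id, author = author, verified = verified, rt = rt, urls = urls)
}

# independent BiCM oracle: brute-force likelihood maximization over the
# full (theta, eta) vector, no degree reduction, no peeling
bicm_oracle_p <- function(B) {
  nll <- function(par) {
    th <- par[seq_len(nrow(B))]
    et <- par[nrow(B) + seq_len(ncol(B))]
    p <- 1 / (1 + exp(outer(th, et, "+")))
    -sum(B * log(p) + (1 - B) * log(1 - p))
  }
  o <- stats::optim(rep(0, nrow(B) + ncol(B)), nll, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  1 / (1 + exp(outer(o$par[seq_len(nrow(B))],
                     o$par[nrow(B) + seq_len(ncol(B))], "+")))
}

# exact Poisson-binomial survival by enumeration over all 2^n outcomes
pb_sf_enum <- function(probs, v) {
  n <- length(probs)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= v) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
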