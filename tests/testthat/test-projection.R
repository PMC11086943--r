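test_that("count_vmotifs matches the B B^T oracle and handles both layers", {
  g <- random_bipartite(5, 6, 0.5, seed = 11)
  tab <- count_vmotifs(g, "top")
  V <- tcrossprod(g$biadjacency)
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$v[r], V[tab$i[r], tab$j[r]])
  }
  expect_equal(nrow(tab), choose(5, 2))
  expect_equal(nrow(count_vmotifs(g, "bottom")), choose(6, 2))

  # identical neighbor sets / disjoint neighbor sets
  B <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0), c(0, 0, 0, 1))
  t2 <- count_vmotifs(bipartite_graph(B), "top")
  expect_equal(t2$v[t2$i == "t1" & t2$j == "t2"], 3)
  expect_equal(t2$v[t2$i == "t1" & t2$j == "t3"], 0)

  expect_error(count_vmotifs(bipartite_graph(matrix(1, 1, 3)), "top"), "2 nodes")
})

test_that("poisson_binomial_sf: exact values, edge cases, enumeration oracle", {
  expect_equal(poisson_binomial_sf(c(0.5, 0.5), 2), 0.25)
  expect_equal(poisson_binomial_sf(c(0.2, 0.9), 0), 1)
  expect_equal(poisson_binomial_sf(c(0.2, 0.3, 0.5), 2), 0.25)
  expect_equal(poisson_binomial_sf(c(0.5, 0.5), 3), 0)
  expect_error(poisson_binomial_sf(c(0.5), -1), "non-negative")
  expect_error(poisson_binomial_sf(c(1.5), 1), "\\[0, 1\\]")

  # probabilities exactly 1 count as certain successes
  expect_equal(poisson_binomial_sf(c(1, 1, 0.5), 2), 1)
  expect_equal(poisson_binomial_sf(c(1, 0.5), 2), 0.5)

  # random instances up to 12 trials vs full-outcome enumeration
  set.seed(21)
  for (r in 1:20) {
    n <- sample(1:12, 1)
    probs <- stats::runif(n)
    v <- sample(0:n, 1)
    expect_equal(poisson_binomial_sf(probs, v), pb_sf_enum(probs, v),
                 tolerance = 1e-9)
  }
})

test_that("normal approximation only engages above the threshold, flagged", {
  probs <- rep(0.3, 50)
  exact <- poisson_binomial_sf(probs, 20)
  approx <- poisson_binomial_sf(probs, 20, approx_threshold = 10)
  expect_true(isTRUE(attr(approx, "approx")))
  expect_null(attr(exact, "approx"))
  expect_equal(as.numeric(approx), exact, tolerance = 0.05)
})

test_that("DP p-values agree with Monte-Carlo from sample_graph", {
  g <- random_bipartite(4, 6, 0.5, seed = 3)
  m <- fit_bicm(g)
  probs <- m$p[1, ] * m$p[2, ]
  n_draw <- 10000
  set.seed(55)
  hits <- numeric(n_draw)
  for (d in seq_len(n_draw)) {
    s <- sample_graph(m)
    hits[d] <- sum(s$biadjacency[1, ] * s$biadjacency[2, ])
  }
  for (v in 1:3) {
    p_dp <- poisson_binomial_sf(probs, v)
    p_mc <- mean(hits >= v)
    se <- sqrt(p_dp * (1 - p_dp) / n_draw)
    expect_lt(abs(p_dp - p_mc), 3 * se + 1e-12)
  }
})

test_that("bh_select matches brute force over all k", {
  bh_brute <- function(p, alpha) {
    m <- length(p)
    ps <- sort(p)
    khat <- 0
    for (k in seq_len(m)) if (ps[k] <= k * alpha / m) khat <- k
    if (khat == 0) rep(FALSE, m) else p <= ps[khat]
  }
  sel <- bh_select(c(0.001, 0.01, 0.03, 0.04), 0.05)
  expect_equal(sel$reject, rep(TRUE, 4))
  expect_equal(sel$threshold, 0.04)

  expect_equal(bh_select(rep(1, 5), 0.05)$reject, rep(FALSE, 5))
  expect_true(bh_select(0.04, 0.05)$reject)

  set.seed(13)
  for (r in 1:25) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    alpha <- stats::runif(1, 0.01, 0.2)
    expect_equal(bh_select(p, alpha)$reject, bh_brute(p, alpha))
  }
  expect_error(bh_select(c(0.1), 1.5), "alpha")
  expect_error(bh_select(numeric(0), 0.05), "nonempty")
})

test_that("validate_projection finds a planted pair and nothing else", {
  # 2 users sharing 10 of 10 URLs among 50 users sharing ~1 random URL each
  set.seed(2024)
  n_bg <- 50
  pool <- paste0("url", 1:100)
  top <- c(rep("A", 10), rep("B", 10))
  bottom <- c(paste0("shared", 1:10), paste0("shared", 1:10))
  for (u in paste0("bg", seq_len(n_bg))) {
    top <- c(top, u)
    bottom <- c(bottom, sample(pool, 1))
  }
  g <- bipartite_from_edges(top, bottom)
  m <- fit_bicm(g)
  proj <- validate_projection(g, m, "top", alpha = 0.05)
  tab <- proj$table
  expect_true(tab$validated[tab$i == "A" & tab$j == "B"])
  expect_true(all(c("A", "B") %in% proj$validated_nodes))
  expect_lt(length(proj$validated_nodes) / (n_bg + 2), 0.2)

  # projection invariant: edges iff p <= threshold
  expect_true(all(tab$pvalue[tab$validated] <= proj$threshold))
  if (any(!tab$validated)) {
    expect_true(all(tab$pvalue[!tab$validated] > proj$threshold))
  }
})

test_that("complete bipartite graph validates nothing", {
  g <- bipartite_graph(matrix(1, 4, 5))
  m <- fit_bicm(g)
  proj <- validate_projection(g, m, "top")
  expect_equal(sum(proj$table$validated), 0)
  expect_true(all(proj$table$pvalue == 1))
})

test_that("validated edge set is monotone non-increasing in alpha", {
  g <- random_bipartite(10, 15, 0.4, seed = 17)
  m <- fit_bicm(g)
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  edges <- lapply(alphas, function(a) {
    t <- validate_projection(g, m, "top", alpha = a)$table
    paste(t$i, t$j)[t$validated]
  })
  for (i in 2:length(alphas)) {
    expect_true(all(edges[[i]] %in% edges[[i - 1]]))
  }
})

test_that("FDR sanity: exchangeable null validates few pairs on average", {
  # all-equal link probabilities: any validated pair is a false discovery
  fracs <- numeric(6)
  for (s in seq_len(6)) {
    g <- random_bipartite(8, 30, 0.3, seed = 100 + s)
    m <- fit_bicm(g)
    t <- validate_projection(g, m, "top", alpha = 0.05)$table
    fracs[s] <- mean(t$validated)
  }
  expect_lte(mean(fracs), 0.05)
})
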