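test_that("uniform-degree graphs get the closed-form uniform probability", {
  # 2x2, all degrees 1: p = L/(N_top * N_bot) = 0.5 everywhere
  g <- bipartite_graph(matrix(c(1, 0, 0, 1), 2, 2))
  m <- fit_bicm(g, tol = 1e-12)
  expect_equal(unname(m$p), matrix(0.5, 2, 2), tolerance = 1e-10)

  g3 <- bipartite_graph(rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)))
  m3 <- fit_bicm(g3, tol = 1e-12)
  expect_equal(unname(m3$p), matrix(2 / 3, 3, 3), tolerance = 1e-10)
})

test_that("fitted probabilities match the brute-force likelihood oracle", {
  B <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1)) # k = (2,1,1), h = (2,1,1)
  m <- fit_bicm(bipartite_graph(B))
  expect_equal(unname(rowSums(m$p)), c(2, 1, 1), tolerance = 1e-8)
  expect_equal(unname(colSums(m$p)), c(2, 1, 1), tolerance = 1e-8)
  expect_equal(unname(m$p), bicm_oracle_p(B), tolerance = 1e-6)

  B2 <- random_bipartite(5, 7, 0.4, seed = 42)$biadjacency
  m2 <- fit_bicm(bipartite_graph(B2))
  expect_equal(unname(m2$p), bicm_oracle_p(B2), tolerance = 1e-6)
})

test_that("degenerate graphs resolve to exact 0/1 probabilities", {
  # empty graph
  g0 <- bipartite_graph(matrix(0, 3, 4))
  expect_equal(unname(fit_bicm(g0)$p), matrix(0, 3, 4))
  # complete graph
  g1 <- bipartite_graph(matrix(1, 3, 4))
  expect_equal(unname(fit_bicm(g1)$p), matrix(1, 3, 4))
  # mixed: one full row, one empty row, core in between
  B <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  m <- fit_bicm(bipartite_graph(B))
  expect_equal(unname(m$p[1, ]), c(1, 1, 1))
  expect_equal(unname(m$p[2, ]), c(0, 0, 0))
  expect_equal(unname(rowSums(m$p)), rowSums(B), tolerance = 1e-8)
  expect_equal(unname(colSums(m$p)), colSums(B), tolerance = 1e-8)
})

test_that("constraint satisfaction holds on 100 random instances", {
  set.seed(99)
  specs <- data.frame(
    nt = sample(2:8, 100, replace = TRUE),
    nb = sample(2:8, 100, replace = TRUE),
    rate = stats::runif(100, 0.1, 0.9),
    seed = sample.int(1e6, 100)
  )
  worst <- 0
  for (r in seq_len(100)) {
    g <- random_bipartite(specs$nt[r], specs$nb[r], specs$rate[r], specs$seed[r])
    m <- fit_bicm(g)
    res <- max(abs(rowSums(m$p) - g$k), abs(colSums(m$p) - g$h))
    worst <- max(worst, res)
  }
  expect_lte(worst, 1e-8)
})

test_that("3x3 ensemble enumeration: probabilities normalize, degrees match", {
  B <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1))
  g <- bipartite_graph(B)
  m <- fit_bicm(g)
  total <- 0
  exp_k <- numeric(3)
  exp_h <- numeric(3)
  for (mask in 0:511) {
    bits <- matrix(as.integer(intToBits(mask))[1:9], 3, 3)
    gm <- bipartite_graph(bits)
    pr <- graph_probability(m, gm)
    total <- total + pr
    exp_k <- exp_k + pr * rowSums(bits)
    exp_h <- exp_h + pr * colSums(bits)
  }
  expect_equal(total, 1, tolerance = 1e-12)
  expect_equal(exp_k, unname(g$k), tolerance = 1e-8)
  expect_equal(exp_h, unname(g$h), tolerance = 1e-8)
})

test_that("permutation equivariance and degree degeneracy", {
  g <- random_bipartite(6, 5, 0.5, seed = 7)
  m <- fit_bicm(g)
  pr <- sample(6)
  pc <- sample(5)
  gp <- bipartite_graph(g$biadjacency[pr, pc])
  mp <- fit_bicm(gp)
  expect_equal(unname(mp$p), unname(m$p[pr, pc]), tolerance = 1e-10)

  # equal observed degrees => bit-identical multipliers
  same_k <- which(duplicated(g$k) | duplicated(g$k, fromLast = TRUE))
  for (i in same_k) {
    twin <- setdiff(which(g$k == g$k[i]), i)
    expect_identical(unname(m$theta[i]), unname(m$theta[twin[1]]))
  }
})

test_that("log-likelihood: closed forms and local-maximum property", {
  g <- bipartite_graph(matrix(c(1, 0, 0, 1), 2, 2))
  m <- fit_bicm(g)
  expect_equal(log_likelihood(m, g), 4 * log(0.5))

  # p matching g exactly -> likelihood 0
  gfull <- bipartite_graph(matrix(1, 2, 2))
  mfull <- fit_bicm(gfull)
  expect_equal(log_likelihood(mfull, gfull), 0)

  # fitted multipliers are a local maximum on the 3x3 example
  B <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1))
  g3 <- bipartite_graph(B)
  m3 <- fit_bicm(g3)
  ll_at <- function(th, et) {
    p <- 1 / (1 + exp(outer(th, et, "+")))
    sum(B * log(p) + (1 - B) * log(1 - p))
  }
  ll0 <- ll_at(unname(m3$theta), unname(m3$eta))
  set.seed(5)
  for (r in 1:20) {
    d <- stats::rnorm(6, sd = 0.1)
    expect_lte(ll_at(unname(m3$theta) + d[1:3], unname(m3$eta) + d[4:6]),
               ll0 + 1e-12)
  }
  # and the dimension check errors
  expect_error(log_likelihood(m3, g), "incompatible")
})

test_that("sample_graph draws Bernoulli per entry, reproducibly", {
  g <- bipartite_graph(matrix(c(1, 0, 0, 1), 2, 2))
  m <- fit_bicm(g)
  s1 <- sample_graph(m, seed = 123)
  s2 <- sample_graph(m, seed = 123)
  expect_identical(s1$biadjacency, s2$biadjacency)

  m1 <- m; m1$p[] <- 1
  expect_equal(unname(sample_graph(m1, 1)$biadjacency), matrix(1, 2, 2))
  m0 <- m; m0$p[] <- 0
  expect_equal(unname(sample_graph(m0, 1)$biadjacency), matrix(0, 2, 2))

  # mean degrees over 10,000 draws within 3 binomial standard errors of 1
  set.seed(77)
  ks <- matrix(0, 10000, 2)
  for (d in 1:10000) {
    ks[d, ] <- rowSums(matrix(stats::runif(4) < 0.5, 2, 2))
  }
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(max(abs(colMeans(ks) - 1)), 3 * se)
})

test_that("validation errors are raised", {
  expect_error(bipartite_graph(matrix(c(0, 2), 1, 2)), "binary")
  g <- bipartite_graph(matrix(c(1, 0, 0, 1), 2, 2))
  expect_error(fit_bicm(g, tol = -1))
})
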