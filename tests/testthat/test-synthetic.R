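test_that("generator is byte-identical under a fixed config and seed", {
  cfg <- synthetic_config(n_unverified = 30, seed = 44)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$posts, b$dataset$posts)
  expect_identical(a$truth, b$truth)
  # serialized forms are identical too
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_posts(a$dataset, f1)
  write_posts(b$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ground truth satisfies the planted-chamber definition", {
  sim <- generate_dataset(synthetic_config(n_unverified = 50, seed = 9))
  tr <- sim$truth
  for (ch in tr$chambers) {
    # chamber members share a planted NEC and a planted block
    expect_equal(length(unique(tr$nec[ch])), 1)
    expect_equal(length(unique(tr$dico[ch])), 1)
    # and are weakly connected through retweets by construction
    rtu <- rt_undirected(build_retweet_network(sim$dataset))
    sub <- igraph::induced_subgraph(rtu, ch)
    expect_equal(igraph::components(sub)$no, 1)
  }
})

test_that("marginal retweet rates match the configuration within 3 SE", {
  cfg <- synthetic_config(n_unverified = 200, seed = 77)
  sim <- generate_dataset(cfg)
  p <- sim$dataset$posts
  rt <- p[!is.na(p$retweeted_author_id), ]
  # in-block pairs, excluding the planted chamber tree (user-user retweets)
  uv <- rt$retweeted_author_id %in% names(sim$truth$dico)[
    grepl("^v", names(sim$truth$dico))
  ]
  rt <- rt[uv, ]
  same <- substr(rt$author_id, 2, 2) == substr(rt$retweeted_author_id, 2, 2)
  n_pairs_in <- 2 * cfg$n_unverified * cfg$n_verified
  n_pairs_out <- 2 * cfg$n_unverified * cfg$n_verified
  p_in_hat <- sum(same) / n_pairs_in
  p_out_hat <- sum(!same) / n_pairs_out
  se_in <- sqrt(cfg$p_in * (1 - cfg$p_in) / n_pairs_in)
  se_out <- sqrt(cfg$p_out * (1 - cfg$p_out) / n_pairs_out)
  expect_lt(abs(p_in_hat - cfg$p_in), 3 * se_in)
  expect_lt(abs(p_out_hat - cfg$p_out), 3 * se_out)
})

test_that("infeasible and degenerate configurations fail cleanly", {
  expect_error(synthetic_config(nec_users = 500, n_unverified = 100), "larger")
  expect_error(synthetic_config(p_in = 1.5), "rates")
  expect_error(synthetic_config(trust_mix = c(1, 1)), "trust_mix")

  # zero URL-bearing posts -> detect_nec errors cleanly
  cfg <- synthetic_config(n_unverified = 20, bg_share_rate = 0, n_necs = 0,
                          seed = 3)
  sim <- generate_dataset(cfg)
  sim$dataset$posts$urls <- lapply(sim$dataset$posts$urls, function(x) character(0))
  d <- echo_dataset(sim$dataset$posts)
  expect_error(detect_nec(d), "URL")
})

test_that("generated trust labels cover every generated domain", {
  sim <- generate_dataset(synthetic_config(n_unverified = 30, seed = 15))
  urls <- unlist(sim$dataset$posts$urls)
  doms <- canonicalize_url(urls)$domain
  expect_true(all(doms %in% names(sim$trust_labels)))
})
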